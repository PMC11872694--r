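attribute,better,worse,total_satisfaction,category_strength,importance_degree,category
A1,43.12,-61.24,0.78,0.09,2.71,M
A2,51.15,-61.93,0.78,0.08,2.56,O
A3,47.94,-46.79,0.75,0.07,2.11,A
B1,41.74,-52.98,0.74,0.10,2.50,M
B2,33.72,-38.76,0.56,0.05,1.77,I
C1,40.37,-52.98,0.73,0.07,2.39,M
C2,43.58,-52.06,0.74,0.08,2.39,M
C3,34.40,-33.49,0.52,0.01,1.55,I
C4,36.24,-28.21,0.50,0.08,1.36,I
C5,32.80,-34.40,0.50,0.01,1.56,I
D1,47.71,-56.88,0.84,0.09,2.70,M
D2,37.16,-77.98,0.92,0.04,3.30,M
D3,54.36,-74.54,0.92,0.02,3.18,M
D4,41.74,-50.23,0.70,0.06,2.27,I
D5,47.94,-56.19,0.79,0.06,2.53,M
E1,54.36,-40.83,0.76,0.14,2.01,A
E2,41.28,-37.16,0.61,0.04,1.75,I
E3,45.64,-57.57,0.81,0.12,2.67,M
E4,53.90,-44.27,0.78,0.09,2.16,A
F1,48.39,-41.28,0.64,0.02,1.79,I
F2,45.87,-47.02,0.65,0.09,1.97,I
F3,58.49,-57.57,0.82,0.10,2.43,O
F4,40.60,-48.62,0.67,0.03,2.16,I
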