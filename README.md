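# kanodemand

Kano-model analysis of paired-question service demand surveys.

In a Kano questionnaire every service attribute is probed twice: a
*functional* question ("How would you feel if X were provided?") and a
*dysfunctional* question ("… if it were not?"), each answered on the
five-level scale *I like it that way* / *It must be that way* / *I am
neutral* / *I can live with it* / *I dislike it that way*. The 5×5 Kano
evaluation table maps each answer pair to one of six categories: must-be
(M), one-dimensional (O), attractive (A), indifferent (I), reverse (R) or
questionable (Q). `kanodemand` implements the full analysis pipeline for
such surveys — aimed at public-health and service-quality researchers who
need reproducible, auditable Kano analyses rather than spreadsheet
arithmetic — plus seeded synthetic-respondent generators for method testing.

For an attribute with category frequencies $f_M, f_O, f_A, f_I$ (reverse and
questionable answers excluded) and $N = f_M + f_O + f_A + f_I$, the package
computes:

- **Better** (satisfaction coefficient): $\mathrm{SI} = (f_A + f_O)/N$
- **Worse** (dissatisfaction coefficient, Berger convention, reported
  negative): $\mathrm{DI} = -(f_O + f_M)/N$
- **Total satisfaction index**: $(f_M + f_O + f_A)/N$
- **Category strength**: (largest − second-largest of $f_M, f_O, f_A$) / $N$
- **Importance degree**: $\mathrm{ID} = (5 f_M + 3 f_O + 1 f_A + 0 f_I)/N$
- the **modal category** (argmax over M/O/A/I, ties broken M > O > A > I),
  and quadrant assignments on the Better–|Worse| plane.

Reliability diagnostics for the underlying Likert item banks are included:
Cronbach's α (per dimension and overall, for each polarity), the
Kaiser–Meyer–Olkin measure, and Bartlett's test of sphericity.

The package ships a complete case study: the published aggregate results of
a demand survey of 436 older adults covering 23 public sports service
attributes in six dimensions (`sports_demand_counts()`,
`sports_demand_attributes()`, `sports_demand_reference()`). A few
Better/Worse cells of the published table are arithmetically inconsistent
with its own frequency counts; `compare_reference()` reproduces the
formula-consistent values and flags those cells instead of matching them.

## Worked example

```r
library(kanodemand)

# synthesise respondent-level data realising the case-study counts
svy <- generate_from_counts(sports_demand_counts(), seed = 42,
                            manifest = sports_demand_attributes())
svy
#> <kano_survey> 436 respondents x 23 attributes (6 dimensions)

s <- summarize_survey(svy)
s
#> <kano_summary> 23 attributes
#>   category census: M:9  O:2  A:3  I:9
#>   mean importance degree: 2.25 (12 attributes above the mean)
#> # A tibble: 23 x 10
#>   attribute n_classifiable better  worse total_satisfaction category_strength
#> 1 A1                   436  0.431 -0.612              0.782            0.0894
#> 2 A2                   436  0.511 -0.619              0.782            0.0780
#> ...
```

Nine attributes are must-be qualities, two one-dimensional, three
attractive and nine indifferent; the mean importance degree is 2.25 with 12
attributes above it. Attribute A1 has Better 43.12% (43% of classifiable
respondents gain satisfaction from the service) and Worse −61.24% (61%
would be dissatisfied without it), so it sits in the high-|Worse| half of
the better–worse plane — a service to secure before delighting anyone:

```r
q <- quadrant_assign(s$indices)   # thresholds default to the two means
head(q, 3)
#>   attribute better worse_magnitude quadrant               x_threshold y_threshold
#> 1 A1         0.431           0.612 low-better/high-worse        0.501       0.453
#> 2 A2         0.511           0.619 high-better/high-worse       0.501       0.453
#> 3 A3         0.507           0.440 high-better/low-worse        0.501       0.453
plot_better_worse(q)

# full report on disk: indices.csv, summary.json, quadrants.csv, manifest.json
write_results(s, "results/", assignments = q,
              reference = sports_demand_reference(),
              config = list(seed = 42))
```

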