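# Notes on the packaged 34-variable Spearman matrix

`table3_spearman.csv` is a transcription of the published full Spearman
correlation matrix of the adolescent suicide-attempter cohort (n = 267, 34
already-scored questionnaire variables). Entries are printed to three
decimals in the source.

Transcription audit:

- The printed table is almost perfectly symmetric. Exactly one cell pair
  disagrees: (Anx, SDQPrs) is printed as -0.064 in the Anx row but as
  +0.064 in the SDQPrs row. The fixture adopts **-0.064** on both sides.
  All network quantities computed by this package use the absolute value of
  the coefficient, so the sign choice does not affect any result.
- The diagonal is 1.000 throughout; all off-diagonal entries lie in
  [-0.305, 0.704].
- Abbreviation alias: the source legend expands `Etn` as "Anorexia and
  bulimia nervosa" while the diagnostic-interview grouping elsewhere calls
  the same indicator "Eating disorders". The fixture keeps the name `Etn`
  with group `MINI-KID`.
- The matrix, being a rounded transcription, is not guaranteed positive
  semidefinite; `nearest_correlation_matrix()` repairs it before copula
  simulation.
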