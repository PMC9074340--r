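# Independent oracles, kept deliberately separate from the package's own
# implementations: a second transcription of the pattern-score table, a
# brute-force Pearson chi-square via expected counts, and a brute-force
# Cohen's kappa from first principles.

oracle_score <- function(marker, label) {
  key <- paste(marker, label, sep = ":")
  lookup <- c(
    "CK13:A" = 0, "CK13:B" = 1, "CK13:C" = 2,
    "CK17:A" = 0, "CK17:B" = 1, "CK17:C" = 2,
    "KI67:A" = 0, "KI67:B" = 3, "KI67:C" = 3,
    "LN5G2:A1" = 0, "LN5G2:A2" = 0,
    "LN5G2:B" = 4, "LN5G2:C" = 4, "LN5G2:D" = 4
  )
  unname(lookup[key])
}

oracle_total <- function(ck13, ck17, ki67, ln5g2) {
  oracle_score("CK13", ck13) + oracle_score("CK17", ck17) +
    oracle_score("KI67", ki67) + oracle_score("LN5G2", ln5g2)
}

# Pearson chi-square via Sum (O - E)^2 / E over all cells
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Cohen's kappa from a square cross-table
oracle_kappa <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# one-row specimen table shorthand
spt1 <- function(ck13, ck17, ki67, ln5g2, id = "s1", group = "g") {
  specimen_table(id, group, ck13 = ck13, ck17 = ck17, ki67 = ki67, ln5g2 = ln5g2)
}

# identical-rater table built from a specimen table
identical_raters <- function(specimens) {
  rater_pairs(specimens$specimen_id, specimens, specimens)
}
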