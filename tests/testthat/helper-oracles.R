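# Independent oracles kept deliberately naive so they share no code path
# with the implementation they check.

# ISS without sorting: maximum over all 3-region subsets of the sum of
# squared per-region maxima
oracle_iss <- function(profile) {
  subsets <- utils::combn(6, 3)
  max(apply(subsets, 2, function(s) sum(profile[s]^2)))
}

# weighted kappa as an explicit double sum over cells and marginals
oracle_kappa <- function(tab, weighting = "linear") {
  k <- nrow(tab)
  n <- sum(tab)
  po <- 0; pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- if (weighting == "linear") 1 - abs(i - j) / (k - 1)
           else 1 - (i - j)^2 / (k - 1)^2
      po <- po + w * tab[i, j] / n
      pe <- pe + w * (sum(tab[i, ]) / n) * (sum(tab[, j]) / n)
    }
  }
  (po - pe) / (1 - pe)
}

random_count_table <- function(k = 6, max_count = 50) {
  matrix(sample(0:max_count, k * k, replace = TRUE), nrow = k)
}

# brute-force longest-prefix recoder: tries every rule against every
# prefix/tail split of the code
oracle_recode <- function(sig, rules) {
  best <- NULL
  for (i in seq_len(nrow(rules))) {
    pat <- rules$gm_pattern[i]
    for (cut in seq_len(nchar(sig))) {
      if (substr(sig, 1, cut) == pat &&
          (is.null(best) || nchar(pat) > nchar(best$pat)))
        best <- list(pat = pat, target = rules$cm_target[i],
                     tail = substring(sig, cut + 1))
    }
  }
  if (is.null(best)) sig else paste0(best$target, best$tail)
}

# Monte-Carlo rejection rate of the paired TOST at true mean difference 0
mc_tost_power <- function(n, sd, low = -3, high = 3, alpha = 0.05,
                          reps = 4000) {
  hits <- vapply(seq_len(reps), function(i) {
    d <- rnorm(n, 0, sd)
    se <- sd(d) / sqrt(n); df <- n - 1
    pl <- pt((mean(d) - low) / se, df, lower.tail = FALSE)
    pu <- pt((mean(d) - high) / se, df)
    max(pl, pu) <= alpha
  }, logical(1))
  mean(hits)
}

fixture_tables <- function() {
  list(rules = load_recode_rules(icd2iss_fixture("recode_rules.tsv")),
       policies = load_seventh_policies(icd2iss_fixture("seventh_char_policies.tsv")),
       details = load_detail_map(icd2iss_fixture("detail_interpretations.tsv")),
       ais = load_ais_table(icd2iss_fixture("ais_table.tsv")))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_canonical_cm <- function(n = 50) {
  cats <- c(sprintf("S%02d", sample(0:99, n, replace = TRUE)),
            sprintf("T%02d", sample(0:88, n, replace = TRUE)))
  cats <- sample(cats, n)
  vapply(cats, function(cc) {
    sub_len <- sample(0:2, 1)
    subclass <- paste(sample(0:9, sub_len, replace = TRUE), collapse = "")
    pad <- strrep("X", 2 - sub_len)
    seventh <- sample(c(0:9, LETTERS[1:6], "X"), 1)
    enc <- sample(c("A", "D", "S"), 1)
    paste0(cc, ".", subclass, pad, seventh, enc)
  }, character(1), USE.NAMES = FALSE)
}
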