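## Independent oracles used by the test suite. These deliberately avoid the
## package's computational paths: exhaustive enumeration for the rank tests
## and effect size, and direct nested lookups on the shipped table files for
## the REBA composition.

## Two-sided permutation p for the Mann-Whitney U: enumerate every
## assignment of the pooled values to group a.
mwu_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), na)
  u <- apply(idx, 2L, function(i) sum(r[i]) - na * (na + 1) / 2)
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  mean(abs(u - mu) >= abs(obs - mu) - 1e-9)
}

## Cliff's delta by explicit pair enumeration.
cliffs_enum <- function(a, b) {
  gt <- 0L
  lt <- 0L
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1L
    if (x < y) lt <- lt + 1L
  }
  (gt - lt) / (length(a) * length(b))
}

## Long-format transcriptions of the worksheet tables, read straight from
## the shipped plain-text files, plus a scalar nested-lookup composer.
oracle_tabs <- local({
  ext <- function(f) system.file("extdata", f, package = "rebamotion",
                                 mustWork = TRUE)
  list(a = utils::read.table(ext("reba_table_a.tsv"), header = TRUE,
                             comment.char = "#"),
       b = utils::read.table(ext("reba_table_b.tsv"), header = TRUE,
                             comment.char = "#"),
       c = as.matrix(utils::read.table(ext("reba_table_c.tsv"),
                                       comment.char = "#")))
})

oracle_final <- function(neck, trunk, legs, load,
                         ua_l, fa_l, wr_l, ua_r, fa_r, wr_r, act) {
  la <- oracle_tabs$a
  ta <- la$score[la$neck == neck & la$trunk == trunk & la$legs == legs]
  tb <- function(ua, fa, wr) {
    lb <- oracle_tabs$b
    lb$score[lb$upper_arm == ua & lb$forearm == fa & lb$wrist == wr]
  }
  sa <- ta + load
  sb <- max(tb(ua_l, fa_l, wr_l), tb(ua_r, fa_r, wr_r))
  oracle_tabs$c[sa, sb] + act
}
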