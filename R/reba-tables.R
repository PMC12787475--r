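## The three REBA worksheet lookup tables ship as plain-text files under
## inst/extdata and are parsed once per session into dense arrays.

.reba_cache <- new.env(parent = emptyenv())

#' REBA worksheet lookup tables
#'
#' Loads (and caches) the transcription of the published REBA employee
#' assessment worksheet tables: Table A (neck x trunk x legs), Table B
#' (upper arm x forearm x wrist) and Table C (Score A x Score B).
#'
#' @return A list with arrays `a` (3 x 5 x 4), `b` (6 x 2 x 3) and `c`
#'   (12 x 12).
#' @export
reba_tables <- function() {
  if (!is.null(.reba_cache$tables)) return(.reba_cache$tables)
  ext <- function(f) system.file("extdata", f, package = "rebamotion",
                                 mustWork = TRUE)
  long_a <- utils::read.table(ext("reba_table_a.tsv"), header = TRUE,
                              comment.char = "#")
  long_b <- utils::read.table(ext("reba_table_b.tsv"), header = TRUE,
                              comment.char = "#")
  a <- array(NA_integer_, dim = c(3, 5, 4))
  a[cbind(long_a$neck, long_a$trunk, long_a$legs)] <- long_a$score
  b <- array(NA_integer_, dim = c(6, 2, 3))
  b[cbind(long_b$upper_arm, long_b$forearm, long_b$wrist)] <- long_b$score
  cc <- as.matrix(utils::read.table(ext("reba_table_c.tsv"),
                                    comment.char = "#"))
  dimnames(cc) <- NULL
  storage.mode(cc) <- "integer"
  stopifnot(!anyNA(a), !anyNA(b), !anyNA(cc),
            dim(cc)[1] == 12L, dim(cc)[2] == 12L)
  .reba_cache$tables <- list(a = a, b = b, c = cc)
  .reba_cache$tables
}

check_index <- function(x, lo, hi, what) {
  if (!is.numeric(x) || anyNA(x) || any(x != as.integer(x)) ||
      any(x < lo) || any(x > hi)) {
    stop(what, " index out of range [", lo, ", ", hi, "]", call. = FALSE)
  }
  as.integer(x)
}

#' REBA Table A lookup (neck, trunk, legs)
#'
#' @param neck Neck score, 1-3.
#' @param trunk Trunk score, 1-5.
#' @param legs Leg score, 1-4.
#' @return Integer Table A posture score, 1-9. Vectorised.
#' @export
#' @examples
#' lookup_table_a(1, 1, 1)  # 1
#' lookup_table_a(3, 5, 4)  # 9
lookup_table_a <- function(neck, trunk, legs) {
  tab <- reba_tables()$a
  tab[cbind(check_index(neck, 1, 3, "neck"),
            check_index(trunk, 1, 5, "trunk"),
            check_index(legs, 1, 4, "legs"))]
}

#' REBA Table B lookup (upper arm, forearm, wrist)
#'
#' @param upper_arm Upper-arm score, 1-6.
#' @param forearm Forearm score, 1-2.
#' @param wrist Wrist score, 1-3.
#' @return Integer Table B posture score, 1-9. Vectorised.
#' @export
lookup_table_b <- function(upper_arm, forearm, wrist) {
  tab <- reba_tables()$b
  tab[cbind(check_index(upper_arm, 1, 6, "upper_arm"),
            check_index(forearm, 1, 2, "forearm"),
            check_index(wrist, 1, 3, "wrist"))]
}

#' REBA Table C lookup (Score A, Score B)
#'
#' @param score_a Score A (Table A + load score), 1-12.
#' @param score_b Score B (Table B + coupling score), 1-12.
#' @return Integer Table C score, 1-12. Vectorised.
#' @export
lookup_table_c <- function(score_a, score_b) {
  tab <- reba_tables()$c
  tab[cbind(check_index(score_a, 1, 12, "score_a"),
            check_index(score_b, 1, 12, "score_b"))]
}
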