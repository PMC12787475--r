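#' Construct a training plan
#'
#' A training plan is the schedule of scored movement sequences of one
#' classical training session: one row per individual measurement, with the
#' printed cycle counts, the execution multiplier used for the weighted
#' calculations, the duration of one execution block, the number of blocks
#' (right/left sides), and gender applicability.
#'
#' @param rows A data.frame with columns `label`, `phase` (1-3), `cycles`
#'   (free text, descriptive), `executions` (integer multiplier >= 1),
#'   `block_duration_s` (> 0), `n_blocks` (integer >= 1) and `gender`
#'   (`"both"`, `"female_only"`, `"male_only"`).
#' @return A `training_plan` (validated data.frame subclass). The total
#'   duration of a row is `block_duration_s * n_blocks * executions`.
#' @seealso [default_training_plan()], [total_duration()]
#' @export
training_plan <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  needed <- c("label", "phase", "cycles", "executions", "block_duration_s",
              "n_blocks", "gender")
  missing <- setdiff(needed, names(rows))
  if (length(missing)) {
    stop("training plan lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(rows$phase %in% 1:3)) stop("phases must be in 1..3", call. = FALSE)
  if (!all(rows$block_duration_s > 0)) stop("durations must be > 0", call. = FALSE)
  if (!all(rows$executions >= 1) || !all(rows$n_blocks >= 1)) {
    stop("executions and n_blocks must be >= 1", call. = FALSE)
  }
  if (!all(rows$gender %in% c("both", "female_only", "male_only"))) {
    stop("gender must be 'both', 'female_only' or 'male_only'", call. = FALSE)
  }
  rows$duration_s <- rows$block_duration_s * rows$n_blocks * rows$executions
  class(rows) <- c("training_plan", "data.frame")
  rows
}

#' The default classical-training plan
#'
#' The built-in schedule of a condensed 80-minute professional classical
#' ballet training session: phase 1 (barre, supported static work), phase 2
#' (centre work with adagio and pirouettes) and phase 3 (jumps/allegro),
#' with pointe rows for the female dancers and the closing manege jump
#' sequence for the male dancers. Pure load durations sum to 1358 s for the
#' male and 1410 s for the female programme, over 16 and 19 individual
#' measurements respectively.
#'
#' One schedule row ("Port de bras and adagio") is printed in the source
#' schedule as a 72 s right-and-left pair, but the programme totals are only
#' consistent with that block counted once; the plan follows the totals.
#'
#' @return A [training_plan()].
#' @export
default_training_plan <- function() {
  r <- function(label, phase, cycles, executions, dur, n_blocks, gender = "both") {
    data.frame(label = label, phase = phase, cycles = cycles,
               executions = executions, block_duration_s = dur,
               n_blocks = n_blocks, gender = gender,
               stringsAsFactors = FALSE)
  }
  training_plan(rbind(
    ## phase 1: barre
    r("plie_right",            1L, "64 + 8 (balance)",   1L, 150, 1L),
    r("plie_left",             1L, "64 + 8 (balance)",   1L, 150, 1L),
    r("ronds_de_jambe_right",  1L, "36 + 16 (balance)",  1L, 135, 1L),
    r("ronds_de_jambe_left",   1L, "36 + 16 (balance)",  1L, 135, 1L),
    r("battement_frappe",      1L, "32 x 2 (r and l)",   1L,  25, 2L),
    r("adagio_fondu_developpe", 1L, "32 x 2 (r and l)",  1L,  70, 2L),
    r("grand_battement",       1L, "32 x 2 + 8 (balance)", 1L, 37, 2L),
    ## phase 2: centre
    r("port_de_bras_adagio",   2L, "32 x 2 (r and l)",   1L,  72, 1L),
    r("pirouettes_right",      2L, "32",                 3L,  26, 1L),
    r("pirouettes_left",       2L, "32",                 3L,  26, 1L),
    ## phase 3: jumps
    r("warmup_jumps",          3L, "16 x 2 (r and l)",   1L,  13, 2L),
    r("jetes_glissades",       3L, "16 x 2 (r and l)",   3L,  12, 2L),
    r("batterie",              3L, "16 x 2 (r and l)",   2L,  13, 2L),
    r("grand_allegro_right",   3L, "16",                 4L,  17, 1L),
    r("grand_allegro_left",    3L, "16",                 4L,  17, 1L),
    ## gender-specific closing rows
    r("warmup_pointe",         3L, "16 x 2 (r and l)",   1L,  16, 2L, "female_only"),
    r("manege_demi_pointe_right", 3L, "8 x 2",           1L,  10, 1L, "female_only"),
    r("manege_demi_pointe_left",  3L, "8 x 2",           1L,  10, 1L, "female_only"),
    r("manege_pointe_right",   3L, "8 x 2",              1L,  10, 1L, "female_only"),
    r("grand_allegro_manege",  3L, "8",                  1L,  10, 1L, "male_only")
  ))
}

#' Plan rows applicable to one gender
#'
#' @param plan A [training_plan()].
#' @param gender `"female"` or `"male"`.
#' @return The applicable subset of `plan`.
#' @export
plan_for_gender <- function(plan, gender = c("female", "male")) {
  gender <- match.arg(gender)
  keep <- plan$gender == "both" |
    plan$gender == paste0(gender, "_only")
  plan[keep, , drop = FALSE]
}

#' Total pure load duration of a plan for one gender
#'
#' Sums `block_duration_s * n_blocks * executions` over the rows applicable
#' to the gender. For the default plan this reproduces the programme totals
#' of 1358 s (male) and 1410 s (female).
#'
#' @inheritParams plan_for_gender
#' @return Duration in seconds.
#' @export
#' @examples
#' total_duration(default_training_plan(), "male")    # 1358
#' total_duration(default_training_plan(), "female")  # 1410
total_duration <- function(plan, gender = c("female", "male")) {
  if (nrow(plan) == 0L) return(0)
  sum(plan_for_gender(plan, gender)$duration_s)
}

#' @export
print.training_plan <- function(x, ...) {
  cat("<training_plan> ", nrow(x), " rows; total ",
      total_duration(x, "male"), " s (m) / ",
      total_duration(x, "female"), " s (f)\n", sep = "")
  print.data.frame(x[, c("label", "phase", "executions", "block_duration_s",
                         "n_blocks", "gender", "duration_s")],
                   row.names = FALSE)
  invisible(x)
}
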