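#' Round half away from zero
#'
#' Commercial rounding used for all printed dollar amounts: ties go away
#' from zero (`round_half_away(0.5) == 1`, `round_half_away(-0.5) == -1`),
#' unlike base [round()]'s round-half-to-even. Internal arithmetic is never
#' rounded; this is applied at reporting time only.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep (default 0).
#' @return numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' round_half_away(4684.4)      # 4684
#' round_half_away(236138.859)  # 236139
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Parse a probability that may carry a percent sign
#'
#' Configuration files may state probabilities either as proportions
#' (`0.055`) or as percent strings (`"5.5%"`); this normalizes both to a
#' proportion in `[0, 1]`.
#'
#' @param x numeric scalar or character scalar (optionally ending in `%`).
#' @param field name used in error messages.
#' @return numeric proportion.
#' @export
parse_proportion <- function(x, field = "probability") {
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("%$", x)) {
      val <- suppressWarnings(as.numeric(sub("%$", "", x))) / 100
    } else {
      val <- suppressWarnings(as.numeric(x))
    }
  } else if (is.numeric(x)) {
    val <- as.numeric(x)
  } else {
    stop(sprintf("field '%s': cannot interpret value of class %s as a probability",
                 field, class(x)[1]), call. = FALSE)
  }
  if (length(val) != 1L || is.na(val)) {
    stop(sprintf("field '%s': malformed probability value", field), call. = FALSE)
  }
  if (val < 0 || val > 1) {
    stop(sprintf("field '%s': probability %g outside [0, 1]", field, val),
         call. = FALSE)
  }
  val
}

# format a dollar amount for human-readable output (thousands separators)
fmt_usd <- function(x) {
  paste0("$", formatC(round_half_away(x), format = "f", digits = 0,
                      big.mark = ","))
}

# run an expression with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
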