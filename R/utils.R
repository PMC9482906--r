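# Shared helpers: exact-mass arithmetic, error classes, flag handling.

# Monoisotopic masses of the elements occurring in steroid formulas (u).
.MONO_MASS <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048,
  O = 15.9949146196, S = 31.97207100, D = 2.01410177812
)
.PROTON_MASS <- 1.007276466879

#' Monoisotopic mass of a molecular formula
#'
#' Computes the monoisotopic (exact) mass of a molecular formula such as
#' `"C21H30O2"`. Supported elements are C, H, N, O, S and D (deuterium,
#' for isotopically labelled internal standards).
#'
#' @param formula Character vector of molecular formulas.
#' @return Numeric vector of monoisotopic masses (u).
#' @examples
#' monoisotopic_mass("C21H30O2") # progesterone, 314.2246
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    toks <- toks[nzchar(toks)]
    total <- 0
    seen <- 0L
    for (tok in toks) {
      el <- gsub("[0-9]", "", tok)
      n <- gsub("[^0-9]", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.MONO_MASS)) {
        stop("unsupported element '", el, "' in formula '", f, "'", call. = FALSE)
      }
      total <- total + .MONO_MASS[[el]] * n
      seen <- seen + nchar(tok)
    }
    if (seen != nchar(f)) {
      stop("could not parse formula '", f, "'", call. = FALSE)
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Ion m/z for a molecular formula
#'
#' Returns the m/z of the singly charged `[M+H]+` (positive mode) or
#' `[M-H]-` (negative mode) ion.
#'
#' @param formula Character vector of molecular formulas.
#' @param polarity `"positive"` or `"negative"`.
#' @return Numeric vector of m/z values (Th).
#' @export
ion_mz <- function(formula, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  m <- monoisotopic_mass(formula)
  if (polarity == "positive") m + .PROTON_MASS else m - .PROTON_MASS
}

# Structured conditions -------------------------------------------------

sq_error <- function(message, class) {
  stop(structure(
    class = c(class, "steroquant_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

config_error <- function(message) sq_error(message, "steroquant_config_error")
reference_error <- function(message) sq_error(message, "steroquant_reference_error")
data_error <- function(message) sq_error(message, "steroquant_data_error")

# Flags are stored as semicolon-joined strings so they survive CSV round
# trips; empty string means no flags.
join_flags <- function(...) {
  f <- unique(c(...))
  f <- f[nzchar(f)]
  paste(f, collapse = ";")
}

has_flag <- function(flags, flag) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(x) flag %in% x, logical(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
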