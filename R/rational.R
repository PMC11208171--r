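#' Exact rational numbers
#'
#' A small vectorised rational-number class used for all stoichiometric
#' coefficients, flux values and ledger arithmetic in the package. Numerators
#' and denominators are kept as integer-valued doubles and reduced by their
#' greatest common divisor after every operation, so balances close *exactly*
#' (residuals are identically zero, not merely small). The coefficients in
#' the acetogenesis network are tiny, so magnitudes never approach the limit
#' of exact double-held integers (2^53).
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), recycled against `num`.
#' @return An object of class `rational`.
#' @examples
#' rational(33, 10)
#' rational(1, 3) + rational(1, 6)   # 1/2
#' as.numeric(rational(50, 33))
#' @export
rational <- function(num, den = 1) {
  if (length(num) == 0) {
    return(structure(list(num = numeric(0), den = numeric(0)),
                     class = "rational"))
  }
  n <- length(num)
  den <- rep_len(den, n)
  if (any(!is.finite(num)) || any(!is.finite(den))) {
    stop("rational() requires finite integer-valued arguments")
  }
  if (any(num != round(num)) || any(den != round(den))) {
    stop("rational() requires integer-valued numerator and denominator")
  }
  if (any(den == 0)) stop("rational() with zero denominator")
  .rat_norm(structure(list(num = as.numeric(num), den = as.numeric(den)),
                      class = "rational"))
}

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  repeat {
    nz <- which(b != 0)
    if (!length(nz)) break
    r <- a[nz] %% b[nz]
    a[nz] <- b[nz]
    b[nz] <- r
  }
  a
}

.rat_norm <- function(x) {
  s <- ifelse(x$den < 0, -1, 1)
  num <- x$num * s
  den <- abs(x$den)
  g <- .gcd2(num, den)
  g[g == 0] <- 1
  x$num <- num / g
  x$den <- den / g
  x
}

#' @export
is_rational <- function(x) inherits(x, "rational")

.as_rat <- function(x) {
  if (is_rational(x)) return(x)
  if (is.numeric(x)) {
    if (any(x != round(x))) {
      stop("cannot coerce non-integer numeric to rational exactly; ",
           "construct it with rational(p, q)")
    }
    return(rational(x))
  }
  stop("cannot coerce ", class(x)[1], " to rational")
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) {
  structure(list(num = x$num[i], den = x$den[i]), class = "rational")
}

#' @export
`[<-.rational` <- function(x, i, value) {
  value <- .as_rat(value)
  x$num[i] <- value$num
  x$den[i] <- value$den
  x
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), .as_rat)
  structure(list(num = unlist(lapply(parts, `[[`, "num")),
                 den = unlist(lapply(parts, `[[`, "den"))),
            class = "rational")
}

#' @export
rep.rational <- function(x, ...) {
  idx <- rep(seq_along(x$num), ...)
  x[idx]
}

#' @export
as.numeric.rational <- function(x, ...) x$num / x$den

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
as.character.rational <- function(x, ...) {
  ifelse(x$den == 1, format(x$num, scientific = FALSE, trim = TRUE),
         paste0(format(x$num, scientific = FALSE, trim = TRUE), "/",
                format(x$den, scientific = FALSE, trim = TRUE)))
}

#' @export
format.rational <- function(x, ...) as.character(x)

#' @export
print.rational <- function(x, ...) {
  cat("<rational> ", paste(as.character(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {  # unary
    e1 <- .as_rat(e1)
    return(switch(.Generic,
      "-" = structure(list(num = -e1$num, den = e1$den), class = "rational"),
      "+" = e1,
      stop("unary ", .Generic, " not defined for rational")))
  }
  e1 <- .as_rat(e1); e2 <- .as_rat(e2)
  n <- max(length(e1), length(e2))
  if (length(e1) < n) e1 <- rep(e1, length.out = n)
  if (length(e2) < n) e2 <- rep(e2, length.out = n)
  switch(.Generic,
    "+" = .rat_norm(structure(list(num = e1$num * e2$den + e2$num * e1$den,
                                   den = e1$den * e2$den), class = "rational")),
    "-" = .rat_norm(structure(list(num = e1$num * e2$den - e2$num * e1$den,
                                   den = e1$den * e2$den), class = "rational")),
    "*" = .rat_norm(structure(list(num = e1$num * e2$num,
                                   den = e1$den * e2$den), class = "rational")),
    "/" = {
      if (any(e2$num == 0)) stop("division by zero rational")
      .rat_norm(structure(list(num = e1$num * e2$den,
                               den = e1$den * e2$num), class = "rational"))
    },
    "==" = e1$num * e2$den == e2$num * e1$den,
    "!=" = e1$num * e2$den != e2$num * e1$den,
    "<"  = e1$num * e2$den <  e2$num * e1$den,
    "<=" = e1$num * e2$den <= e2$num * e1$den,
    ">"  = e1$num * e2$den >  e2$num * e1$den,
    ">=" = e1$num * e2$den >= e2$num * e1$den,
    stop(.Generic, " not defined for rational"))
}

#' @export
sum.rational <- function(..., na.rm = FALSE) {
  x <- c.rational(...)
  acc <- rational(0)
  for (i in seq_along(x)) acc <- acc + x[i]
  acc
}

#' @export
abs.rational <- function(x) {
  structure(list(num = abs(x$num), den = x$den), class = "rational")
}

#' Parse "p/q" strings into rationals
#'
#' Inverse of `as.character()` on a rational; used by the JSON model
#' serialisation where coefficients travel as `"p/q"` strings.
#'
#' @param x character vector like `"3/2"`, `"-1"`, `"33/10"`.
#' @return A `rational` vector.
#' @export
parse_rational <- function(x) {
  parts <- strsplit(as.character(x), "/", fixed = TRUE)
  num <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[1]), numeric(1)))
  den <- suppressWarnings(
    vapply(parts, function(p) if (length(p) > 1) as.numeric(p[2]) else 1,
           numeric(1)))
  if (any(is.na(num)) || any(is.na(den))) stop("malformed rational string")
  rational(num, den)
}

#' Round half-up at a fixed number of decimals
#'
#' The reporting convention used throughout: exact halves round away from
#' zero (2.65 -> 2.7), unlike base `round()`'s round-half-even. For rational
#' input the rounding is carried out in integer arithmetic, so the reported
#' decimal is exact.
#'
#' @param x numeric or `rational`.
#' @param digits decimals to keep (default 1).
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  if (is_rational(x)) {
    # floor((num * p) / den + 1/2) in exact integer arithmetic
    num2 <- 2 * x$num * p + x$den
    return(floor(num2 / (2 * x$den)) / p)
  }
  sign(x) * floor(abs(x) * p + 0.5) / p
}
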