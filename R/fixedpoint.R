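#' Q-format fixed-point number format
#'
#' A fixed-point format with `int_bits` integer bits (including the sign)
#' and `frac_bits` fractional bits.  A mantissa `raw` represents the real
#' value `raw * 2^-frac_bits`; representable values are
#' `[-2^(int_bits-1), 2^(int_bits-1))`.  Defaults follow the hardware
#' sizing: 15 fractional bits and 8 integer bits (14 on the `h_inf`
#' exponential path).
#'
#' @param int_bits Integer bits, including sign (`>= 1`).
#' @param frac_bits Fractional bits (`>= 0`).
#' @return An object of class `"q_format"`.
#' @examples
#' q_format(8, 15)
#' @export
q_format <- function(int_bits = 8, frac_bits = 15) {
  if (int_bits < 1 || frac_bits < 0) stop("invalid Q format")
  structure(list(int_bits = as.integer(int_bits),
                 frac_bits = as.integer(frac_bits)),
            class = "q_format")
}

#' @export
print.q_format <- function(x, ...) {
  cat(sprintf("Q format: %d integer bits (incl. sign) . %d fraction bits\n",
              x$int_bits, x$frac_bits))
  invisible(x)
}

#' Quantize a real number into a Q format
#'
#' The single rounding mode of the emulator is truncation toward minus
#' infinity (`floor`), matching the behaviour of hardware shift registers.
#'
#' @param x Real value(s), finite.
#' @param fmt A [q_format()].
#' @param overflow `"error"` (default) raises an error when `x` falls
#'   outside the representable range; `"saturate"` clamps to the range.
#' @return A `"qvalue"`: list with integer mantissa `raw` and the format.
#' @examples
#' quantize(0.5, q_format(8, 15))$raw   # 16384
#' quantize(-1e-4, q_format(8, 15))$raw # -4 (floor semantics)
#' @export
quantize <- function(x, fmt = q_format(), overflow = c("error", "saturate")) {
  overflow <- match.arg(overflow)
  if (!all(is.finite(x))) stop("x must be finite")
  raw <- floor(x * 2^fmt$frac_bits)
  lo <- -2^(fmt$int_bits - 1 + fmt$frac_bits)
  hi <- 2^(fmt$int_bits - 1 + fmt$frac_bits) - 1
  bad <- raw < lo | raw > hi
  if (any(bad)) {
    if (overflow == "error")
      stop(sprintf("value %g overflows Q(%d,%d)",
                   x[which(bad)[1]], fmt$int_bits, fmt$frac_bits))
    raw <- pmin(pmax(raw, lo), hi)
  }
  structure(list(raw = raw, fmt = fmt), class = "qvalue")
}

#' @rdname quantize
#' @param q A `"qvalue"`.
#' @export
to_real <- function(q) q$raw * 2^(-q$fmt$frac_bits)

#' @export
print.qvalue <- function(x, ...) {
  cat(sprintf("qvalue Q(%d,%d): raw = %s -> %s\n",
              x$fmt$int_bits, x$fmt$frac_bits,
              paste(utils::head(x$raw, 6), collapse = ", "),
              paste(format(utils::head(to_real(x), 6)), collapse = ", ")))
  invisible(x)
}

#' Bit-width sizing rules
#'
#' `frac_bits_for_precision` gives the smallest fraction width whose
#' resolution `2^-f` meets a required precision; `int_bits_for_range` gives
#' the smallest integer width `w` with `2^w / 2 > max_abs`.  These are the
#' rules used to size the datapaths (precision 0.001 -> 10 fraction bits;
#' range 60 -> 7 integer bits; the 8000 reached inside `h_inf` -> 14).
#'
#' @param p Required precision, `0 < p < 1`.
#' @return Integer bit count.
#' @examples
#' frac_bits_for_precision(0.001) # 10
#' int_bits_for_range(60)         # 7
#' int_bits_for_range(8000)       # 14
#' @export
frac_bits_for_precision <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("precision must be in (0, 1)")
  as.integer(ceiling(-log2(p)))
}

#' @rdname frac_bits_for_precision
#' @param max_abs Largest magnitude the variable reaches (`> 0`).
#' @export
int_bits_for_range <- function(max_abs) {
  if (any(max_abs <= 0)) stop("max_abs must be positive")
  w <- as.integer(ceiling(log2(max_abs) + 1))
  # smallest w with 2^w/2 > max_abs (strict inequality)
  ifelse(2^w / 2 > max_abs, w, w + 1L)
}

#' Canonical signed digit decomposition of a constant
#'
#' Decomposes a constant into a minimal sum of terms `(-1)^k * 2^n`, so a
#' multiplication by the constant becomes a short chain of shifts and
#' adds.  The decomposition targets the quantized mantissa
#' `quantize(constant, fmt)`, so the reconstruction is exact at the working
#' precision even for non-dyadic constants.
#'
#' @param constant Real constant.
#' @param fmt Working [q_format()] (only `frac_bits` matters).
#' @return Data frame with columns `k` (0/1 sign bit) and `n` (signed
#'   exponent): the constant equals `sum((-1)^k * 2^n)`.
#' @examples
#' csd_decompose(10)    # +2^3 +2^1
#' csd_decompose(7)     # +2^3 -2^0
#' csd_decompose(4.375) # +2^2 +2^-2 +2^-3
#' @export
csd_decompose <- function(constant, fmt = q_format(16, 15)) {
  m <- floor(constant * 2^fmt$frac_bits)
  neg <- m < 0
  if (neg) m <- -m
  k <- integer(0); n <- integer(0)
  i <- 0L
  while (m != 0) {
    if (m %% 2 == 1) {
      d <- if (m %% 4 == 3) -1L else 1L
      s <- if (neg) -d else d
      k <- c(k, if (s > 0) 0L else 1L)
      n <- c(n, i - fmt$frac_bits)
      m <- m - d
    }
    m <- m %/% 2
    i <- i + 1L
  }
  data.frame(k = k, n = n)
}

#' Shift-add constant multiplication
#'
#' Multiplies a fixed-point value by a constant using its canonical signed
#' digit terms: a sum of shifted copies of the operand, every right shift
#' truncating toward minus infinity.  This is the emulator's model of a
#' hardware shift-add constant multiplier.
#'
#' @param x A `"qvalue"` (vector raw allowed).
#' @param terms Output of [csd_decompose()], or a real constant that is
#'   decomposed with `x`'s format.
#' @return A `"qvalue"` in `x`'s format.
#' @export
const_mult <- function(x, terms) {
  if (!inherits(x, "qvalue")) stop("x must be a qvalue")
  if (is.numeric(terms))
    terms <- csd_decompose(terms, q_format(32, x$fmt$frac_bits))
  acc <- 0
  for (j in seq_len(nrow(terms))) {
    sgn <- if (terms$k[j] == 0) 1 else -1
    sh <- terms$n[j]
    t <- if (sh >= 0) x$raw * 2^sh else x$raw %/% 2^(-sh)
    acc <- acc + sgn * t
  }
  structure(list(raw = acc, fmt = x$fmt), class = "qvalue")
}

#' Functional shift multiplier
#'
#' Variable-by-variable multiplication built from a bus splitter and
#' conditionally shifted copies of the other operand: one operand is split
#' into bits, each set bit contributes the other operand shifted by that
#' bit's position, and the full-width sum is truncated once into the output
#' format.  The summation is exact at full width, so the result equals the
#' mantissa product truncated into `out_fmt`.  By the hardware convention
#' the slower-varying operand is the one split.
#'
#' @param a,b `"qvalue"` operands (vector raw allowed).
#' @param out_fmt Output [q_format()]; defaults to `a`'s format.
#' @param overflow Overflow policy, as in [quantize()].
#' @return A `"qvalue"` in `out_fmt`.
#' @export
fsm_mult <- function(a, b, out_fmt = a$fmt, overflow = c("error", "saturate")) {
  overflow <- match.arg(overflow)
  fa <- a$fmt$frac_bits; fb <- b$fmt$frac_bits; fo <- out_fmt$frac_bits
  raw <- (a$raw * b$raw) %/% 2^(fa + fb - fo)
  lo <- -2^(out_fmt$int_bits - 1 + fo); hi <- -lo - 1
  bad <- raw < lo | raw > hi
  if (any(bad)) {
    if (overflow == "error") stop("fsm_mult overflow")
    raw <- pmin(pmax(raw, lo), hi)
  }
  structure(list(raw = raw, fmt = out_fmt), class = "qvalue")
}
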