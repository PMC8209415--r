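# Sparse trivariate polynomial helpers used by the distortion-field model.
# A polynomial is a data.frame with integer exponent columns i, j, k (for
# x, y, z) and a numeric coefficient column c. Kept internal: users build
# fields through radial_gnl() / parabolic_b0() or pass their own monomial
# tables in the same shape.

poly_new <- function(i = integer(), j = integer(), k = integer(),
                     c = numeric()) {
  data.frame(i = as.integer(i), j = as.integer(j), k = as.integer(k),
             c = as.numeric(c))
}

poly_zero <- function() poly_new()

poly_simplify <- function(p) {
  if (nrow(p) == 0L) return(p)
  key <- paste(p$i, p$j, p$k, sep = ",")
  cs <- tapply(p$c, key, sum)
  ex <- do.call(rbind, lapply(strsplit(names(cs), ",", fixed = TRUE),
                              as.integer))
  out <- poly_new(ex[, 1L], ex[, 2L], ex[, 3L], as.numeric(cs))
  out <- out[abs(out$c) > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

poly_add <- function(a, b) poly_simplify(rbind(a, b))

poly_scale <- function(p, s) {
  p$c <- p$c * s
  p
}

poly_mul <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(poly_zero())
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  poly_simplify(poly_new(a$i[ia] + b$i[ib], a$j[ia] + b$j[ib],
                         a$k[ia] + b$k[ib], a$c[ia] * b$c[ib]))
}

# Evaluate at vectors of coordinates (mm); returns a numeric vector.
poly_eval <- function(p, x, y, z) {
  acc <- numeric(length(x))
  if (nrow(p) == 0L) return(acc)
  for (r in seq_len(nrow(p))) {
    term <- rep(p$c[r], length(x))
    if (p$i[r] > 0L) term <- term * x^p$i[r]
    if (p$j[r] > 0L) term <- term * y^p$j[r]
    if (p$k[r] > 0L) term <- term * z^p$k[r]
    acc <- acc + term
  }
  acc
}

poly_has_constant <- function(p) {
  nrow(p) > 0L && any(p$i == 0L & p$j == 0L & p$k == 0L & p$c != 0)
}

poly_check <- function(p, what = "polynomial") {
  if (!is.data.frame(p) || !all(c("i", "j", "k", "c") %in% names(p)))
    stop(what, " must be a data.frame with columns i, j, k, c", call. = FALSE)
  if (nrow(p) > 0L && (any(p$i < 0) || any(p$j < 0) || any(p$k < 0)))
    stop(what, " exponents must be non-negative", call. = FALSE)
  invisible(p)
}
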