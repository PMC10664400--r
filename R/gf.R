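# Exact arithmetic over the prime field GF(p), p = 67108859 (< 2^26, so all
# products of residues are exact in double precision). Used by the structural
# rank test: evaluating a symbolic Jacobian at a random integer point and
# Gauss-eliminating mod p gives the generic rank with no floating tolerance.

.gf_p <- 67108859

gf_mod <- function(x) x %% .gf_p

gf_mul <- function(a, b) (a * b) %% .gf_p

gf_pow <- function(a, k) {
  k <- as.integer(k)
  if (k < 0L) return(gf_pow(gf_inv(a), -k))
  r <- 1
  a <- gf_mod(a)
  while (k > 0L) {
    if (k %% 2L == 1L) r <- gf_mul(r, a)
    a <- gf_mul(a, a)
    k <- k %/% 2L
  }
  r
}

gf_inv <- function(a) {
  a <- gf_mod(a)
  if (a == 0) stop(errorCondition("division by zero in GF(p) evaluation",
                                  class = c("odeident_gf_zero", "odeident_error")))
  gf_pow(a, .gf_p - 2)
}

# Residue of a real constant: exact for integers; decimal/float literals are
# rationalized by continued fractions (denominator <= 1e7, error < 1e-12).
gf_const <- function(v) {
  if (v < 0) return(gf_mod(-gf_const(-v)))
  if (v == round(v) && abs(v) < 2^52) return(gf_mod(v))
  num <- v; den <- 1
  a0 <- floor(v); h0 <- 1; h1 <- a0; k0 <- 0; k1 <- 1
  frac <- v - a0
  while (abs(h1 / k1 - v) > 1e-12 && k1 < 1e7) {
    frac <- 1 / frac
    ai <- floor(frac)
    frac <- frac - ai
    h2 <- ai * h1 + h0; k2 <- ai * k1 + k0
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (frac == 0) break
  }
  if (abs(h1 / k1 - v) > 1e-9) {
    stop(errorCondition(sprintf("constant %g has no small rational form", v),
                        class = c("odeident_gf_irrational", "odeident_error")))
  }
  gf_mul(gf_mod(h1), gf_inv(k1))
}

# Evaluate an expression over GF(p). `env` maps symbol names to residues.
# Transcendental subcalls (exp/log/sqrt) get memoized random residues keyed by
# the residue of their argument: sound for generic-rank purposes because such
# values are algebraically independent of the rational point.
gf_eval <- function(e, env, memo) {
  if (is.numeric(e)) return(gf_const(e))
  if (is.symbol(e)) {
    nm <- as.character(e)
    v <- env[[nm]]
    if (is.null(v)) stop(sprintf("unbound symbol '%s' in GF evaluation", nm))
    return(v)
  }
  fn <- as.character(e[[1L]])
  if (fn == "(") return(gf_eval(e[[2L]], env, memo))
  if (fn == "-" && length(e) == 2L) return(gf_mod(-gf_eval(e[[2L]], env, memo)))
  if (fn == "+" && length(e) == 2L) return(gf_eval(e[[2L]], env, memo))
  if (fn %in% c("exp", "log", "sqrt")) {
    a <- gf_eval(e[[2L]], env, memo)
    key <- paste0(fn, ":", format(a, scientific = FALSE))
    v <- memo$vals[[key]]
    if (is.null(v)) {
      v <- gf_mod(floor(memo$rng() * (.gf_p - 2)) + 1)
      memo$vals[[key]] <- v
    }
    return(v)
  }
  a <- gf_eval(e[[2L]], env, memo)
  b <- gf_eval(e[[3L]], env, memo)
  switch(fn,
    "+" = gf_mod(a + b),
    "-" = gf_mod(a - b),
    "*" = gf_mul(a, b),
    "/" = gf_mul(a, gf_inv(b)),
    "^" = {
      k <- eval(e[[3L]], baseenv())
      if (!is.numeric(k) || k != round(k)) {
        stop(errorCondition("non-integer exponent in exact evaluation",
                            class = c("odeident_gf_irrational", "odeident_error")))
      }
      gf_pow(a, k)
    },
    stop(sprintf("unsupported function '%s' in GF evaluation", fn))
  )
}

# Memo container with its own deterministic RNG stream (independent of the
# global RNG state).
gf_memo <- function(seed) {
  state <- seed
  rng <- function() {
    # Lehmer / Park-Miller minimal standard generator, exact in doubles.
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
  list(vals = new.env(parent = emptyenv()), rng = rng)
}

# Rank of a numeric matrix of residues via Gaussian elimination mod p.
gf_rank <- function(M) {
  if (length(M) == 0L) return(0L)
  M <- gf_mod(M)
  nr <- nrow(M); nc <- ncol(M)
  rank <- 0L
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(M[row:nr, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(piv, row), ] <- M[c(row, piv), ]
    M[row, ] <- gf_mul(M[row, ], gf_inv(M[row, col]))
    for (r in seq_len(nr)) {
      if (r != row && M[r, col] != 0) {
        M[r, ] <- gf_mod(M[r, ] - gf_mul(M[r, col], M[row, ]))
      }
    }
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}
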