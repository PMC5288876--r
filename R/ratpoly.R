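# Exact symbolic arithmetic: rationals, multivariate polynomials over Q,
# and rational functions.  This is the minimal computer-algebra substrate
# needed by the center-manifold reduction; coefficients are kept exact so
# that structurally-vanishing manifold coefficients cancel to literal zero
# rather than to rounding noise.
#
# Rationals ("qn") are length-2 doubles c(num, den), den > 0, reduced.
# Doubles hold integers exactly below 2^53; every operation reduces by the
# gcd and aborts loudly if a numerator or denominator leaves the exact
# range, so silent precision loss is impossible.

.qn_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

.qn_check <- function(x) {
  if (abs(x) >= 2^53)
    stop("exact rational arithmetic overflow (integer > 2^53); ",
         "supply parameters as simpler rationals", call. = FALSE)
  x
}

qn <- function(num, den = 1) {
  if (den == 0) stop("rational with zero denominator", call. = FALSE)
  if (num == 0) return(c(0, 1))
  if (den < 0) { num <- -num; den <- -den }
  g <- .qn_gcd(num, den)
  c(.qn_check(num / g), .qn_check(den / g))
}

qn_add <- function(a, b) qn(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
qn_sub <- function(a, b) qn(a[1] * b[2] - b[1] * a[2], a[2] * b[2])
qn_mul <- function(a, b) {
  # cross-reduce first to keep intermediates small
  g1 <- .qn_gcd(a[1], b[2]); g2 <- .qn_gcd(b[1], a[2])
  if (g1 == 0) g1 <- 1
  if (g2 == 0) g2 <- 1
  qn((a[1] / g1) * (b[1] / g2), (a[2] / g2) * (b[2] / g1))
}
qn_div <- function(a, b) {
  if (b[1] == 0) stop("rational division by zero", call. = FALSE)
  qn_mul(a, c(b[2], b[1]))
}
qn_neg <- function(a) c(-a[1], a[2])
qn_is_zero <- function(a) a[1] == 0
qn_num <- function(a) a[1] / a[2]

#' Convert a decimal to a small exact rational
#'
#' Uses a continued-fraction expansion to find the smallest-denominator
#' rational within `tol` (relative) of `x`.  Decimal model parameters such
#' as 0.28 or 0.012061855670103093 recover their exact intended values
#' (7/25 and 117/9700) this way before entering exact symbolic work.
#'
#' @param x a finite numeric scalar
#' @param tol relative tolerance of the reconstruction
#' @return length-2 numeric `c(num, den)`
#' @keywords internal
qn_from_num <- function(x, tol = 1e-12) {
  if (x == round(x)) return(qn(x))
  sgn <- sign(x); x <- abs(x)
  # continued fraction convergents
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; r <- x
  for (i in 1:64) {
    a <- floor(r)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > 2^40) break
    if (abs(h / k - x) <= tol * x) return(qn(sgn * h, k))
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    fr <- r - a
    if (fr < 1e-15) break
    r <- 1 / fr
  }
  stop("cannot represent ", x, " as an exact small rational", call. = FALSE)
}

## ---- multivariate polynomials over Q -------------------------------------

.mp_key <- function(e) {
  if (length(e) == 0L) return("1")
  e <- e[order(names(e))]
  paste(names(e), e, sep = "^", collapse = "*")
}

mp_zero <- function() structure(list(terms = list()), class = "cmt_mpoly")

mp_const <- function(q) {
  if (is.numeric(q) && length(q) == 1L) q <- qn_from_num(q)
  if (qn_is_zero(q)) return(mp_zero())
  structure(list(terms = structure(list(list(e = integer(0), q = q)),
                                   names = "1")),
            class = "cmt_mpoly")
}

mp_sym <- function(name, pow = 1L) {
  e <- structure(as.integer(pow), names = name)
  structure(list(terms = structure(list(list(e = e, q = c(1, 1))),
                                   names = .mp_key(e))),
            class = "cmt_mpoly")
}

mp_is_zero <- function(p) length(p$terms) == 0L

mp_add <- function(a, b) {
  terms <- a$terms
  for (k in names(b$terms)) {
    tb <- b$terms[[k]]
    if (is.null(terms[[k]])) {
      terms[[k]] <- tb
    } else {
      s <- qn_add(terms[[k]]$q, tb$q)
      if (qn_is_zero(s)) terms[[k]] <- NULL else terms[[k]]$q <- s
    }
  }
  structure(list(terms = terms), class = "cmt_mpoly")
}

mp_neg <- function(a) {
  for (k in names(a$terms)) a$terms[[k]]$q <- qn_neg(a$terms[[k]]$q)
  a
}

mp_sub <- function(a, b) mp_add(a, mp_neg(b))

.mp_exp_mul <- function(e1, e2) {
  if (length(e1) == 0L) return(e2)
  if (length(e2) == 0L) return(e1)
  vars <- union(names(e1), names(e2))
  e <- structure(integer(length(vars)), names = vars)
  e[names(e1)] <- e[names(e1)] + e1
  e[names(e2)] <- e[names(e2)] + e2
  e[e != 0L]
}

mp_mul <- function(a, b) {
  out <- list()
  for (ta in a$terms) for (tb in b$terms) {
    e <- .mp_exp_mul(ta$e, tb$e)
    k <- .mp_key(e)
    q <- qn_mul(ta$q, tb$q)
    if (is.null(out[[k]])) {
      out[[k]] <- list(e = e, q = q)
    } else {
      s <- qn_add(out[[k]]$q, q)
      if (qn_is_zero(s)) out[[k]] <- NULL else out[[k]]$q <- s
    }
  }
  structure(list(terms = out), class = "cmt_mpoly")
}

mp_scale <- function(a, q) {
  if (qn_is_zero(q)) return(mp_zero())
  for (k in names(a$terms)) a$terms[[k]]$q <- qn_mul(a$terms[[k]]$q, q)
  a
}

mp_pow <- function(a, n) {
  out <- mp_const(qn(1))
  for (i in seq_len(n)) out <- mp_mul(out, a)
  out
}

mp_eval <- function(p, env) {
  tot <- 0
  for (t in p$terms) {
    v <- qn_num(t$q)
    for (nm in names(t$e)) {
      if (is.na(env[nm])) stop("no value for symbol ", nm, call. = FALSE)
      v <- v * env[[nm]]^t$e[[nm]]
    }
    tot <- tot + v
  }
  tot
}

mp_vars <- function(p) {
  vs <- character(0)
  for (t in p$terms) vs <- union(vs, names(t$e))
  sort(vs)
}

# exact division a / b; returns NULL when b does not divide a.
# Single-divisor multivariate division under lexicographic order: the
# remainder vanishes exactly when a lies in the principal ideal (b).
# Monomials are compared through a packed integer key (lexicographic in
# the sorted variable order), and two graded-degree prechecks reject
# most non-divisible inputs without running the division loop: in a
# domain the minimal/maximal total-degree components multiply, so
# divisibility requires mindeg(a) >= mindeg(b) and maxdeg(a) >= maxdeg(b),
# and likewise per-variable maximal exponents.
mp_divexact <- function(a, b) {
  if (mp_is_zero(b)) stop("polynomial division by zero", call. = FALSE)
  if (mp_is_zero(a)) return(mp_zero())
  vars <- sort(union(mp_vars(a), mp_vars(b)))
  nv <- length(vars)
  if (nv == 0L)
    return(mp_const(qn_div(a$terms[[1]]$q, b$terms[[1]]$q)))
  tots_a <- vapply(a$terms, function(t) sum(t$e), 0)
  tots_b <- vapply(b$terms, function(t) sum(t$e), 0)
  if (min(tots_a) < min(tots_b) || max(tots_a) < max(tots_b)) return(NULL)
  vmax <- function(p) {
    m <- structure(numeric(nv), names = vars)
    for (t in p$terms) {
      nm <- names(t$e)
      m[nm] <- pmax(m[nm], t$e)
    }
    m
  }
  if (any(vmax(a) < vmax(b))) return(NULL)
  base <- max(c(tots_a, tots_b, 1)) + 1
  weights <- structure(base^((nv - 1):0), names = vars)
  if (base^nv >= 2^53)
    stop("polynomial degree too large for exact division", call. = FALSE)
  pack <- function(p) vapply(p$terms, function(t) {
    if (length(t$e) == 0L) 0 else sum(weights[names(t$e)] * t$e)
  }, 0)
  ib <- which.max(pack(b))
  ltb <- b$terms[[ib]]
  eb <- structure(integer(nv), names = vars)
  eb[names(ltb$e)] <- ltb$e
  quo <- mp_zero(); rem <- a
  for (guard in seq_len(20000L)) {
    if (mp_is_zero(rem)) return(quo)
    ir <- which.max(pack(rem))
    ltr <- rem$terms[[ir]]
    er <- structure(integer(nv), names = vars)
    er[names(ltr$e)] <- ltr$e
    if (any(er < eb)) return(NULL)
    e <- er - eb
    e <- e[e != 0L]
    term <- structure(list(terms = structure(
      list(list(e = e, q = qn_div(ltr$q, ltb$q))), names = .mp_key(e))),
      class = "cmt_mpoly")
    quo <- mp_add(quo, term)
    rem <- mp_sub(rem, mp_mul(term, b))
  }
  NULL
}

mp_format <- function(p) {
  if (mp_is_zero(p)) return("0")
  ks <- sort(names(p$terms))
  parts <- vapply(ks, function(k) {
    t <- p$terms[[k]]
    co <- if (t$q[2] == 1) sprintf("%g", t$q[1]) else
      sprintf("%g/%g", t$q[1], t$q[2])
    mono <- if (length(t$e) == 0L) "" else
      paste(vapply(seq_along(t$e), function(i) {
        if (t$e[i] == 1L) names(t$e)[i] else
          paste0(names(t$e)[i], "^", t$e[i])
      }, ""), collapse = "*")
    if (mono == "") co
    else if (co == "1") mono
    else if (co == "-1") paste0("-", mono)
    else paste0(co, "*", mono)
  }, "")
  out <- unname(parts[1])
  for (p2 in unname(parts[-1])) {
    out <- if (startsWith(p2, "-")) paste0(out, " - ", substring(p2, 2))
    else paste0(out, " + ", p2)
  }
  out
}

## ---- rational functions ---------------------------------------------------
#
# A rational function is stored as   num / prod_i f_i^{k_i}
# with the denominator kept as a list of primitive polynomial factors.
# Keeping the factored form (rather than an expanded denominator) makes
# cancellation a matter of exact trial division by each factor, which is
# what keeps coefficient growth under control without a full multivariate
# gcd.  Numeric content lives in the numerator.

.mp_content_qn <- function(p) {
  # numeric content gcd(numerators)/lcm(denominators) of the coefficients
  gn <- 0; gl <- 1
  for (t in p$terms) {
    gn <- .qn_gcd(gn, t$q[1])
    gl <- gl * t$q[2] / .qn_gcd(gl, t$q[2])
  }
  if (gn == 0) gn <- 1
  qn(gn, gl)
}

# normalise a polynomial to primitive form (content 1, first-key term
# positive); returns list(prim, scale) with p = scale * prim
.mp_primitive <- function(p) {
  ct <- .mp_content_qn(p)
  lead <- p$terms[[sort(names(p$terms))[1]]]$q
  if (lead[1] < 0) ct <- qn_neg(ct)
  list(prim = mp_scale(p, qn_div(c(1, 1), ct)), scale = ct)
}

.mp_fingerprint <- function(p) {
  ks <- sort(names(p$terms))
  paste(vapply(ks, function(k) {
    q <- p$terms[[k]]$q
    paste0(k, ":", q[1], "/", q[2])
  }, ""), collapse = "|")
}

rf <- function(num, den = NULL) {
  if (is.null(den)) den <- list()
  if (mp_is_zero(num)) den <- list()
  structure(list(num = num, den = den), class = "cmt_rfun")
}

rf_const <- function(q) rf(mp_const(q))
rf_sym <- function(name) rf(mp_sym(name))
rf_is_zero <- function(x) mp_is_zero(x$num)

# cancel denominator factors that exactly divide the numerator
.rf_cancel <- function(x) {
  if (mp_is_zero(x$num)) return(rf(mp_zero()))
  den <- list()
  for (f in x$den) {
    k <- f$k
    while (k > 0L) {
      q <- mp_divexact(x$num, f$f)
      if (is.null(q)) break
      x$num <- q
      k <- k - 1L
    }
    if (k > 0L) den[[length(den) + 1L]] <- list(f = f$f, k = k, id = f$id)
  }
  # constant factors fold into the numerator
  keep <- list()
  for (f in den) {
    if (length(f$f$terms) == 1L && length(f$f$terms[[1]]$e) == 0L) {
      q <- f$f$terms[[1]]$q
      for (i in seq_len(f$k))
        x$num <- mp_scale(x$num, qn_div(c(1, 1), q))
    } else keep[[length(keep) + 1L]] <- f
  }
  rf(x$num, keep)
}

.rf_den_factor <- function(p) {
  pr <- .mp_primitive(p)
  list(f = pr$prim, scale = pr$scale, id = .mp_fingerprint(pr$prim))
}

.rf_den_merge <- function(d1, d2) {
  out <- d1
  for (f in d2) {
    hit <- FALSE
    for (i in seq_along(out)) if (out[[i]]$id == f$id) {
      out[[i]]$k <- out[[i]]$k + f$k; hit <- TRUE; break
    }
    if (!hit) out[[length(out) + 1L]] <- f
  }
  out
}

rf_mul <- function(a, b) {
  if (rf_is_zero(a) || rf_is_zero(b)) return(rf(mp_zero()))
  .rf_cancel(rf(mp_mul(a$num, b$num), .rf_den_merge(a$den, b$den)))
}

rf_neg <- function(a) { a$num <- mp_neg(a$num); a }

rf_add <- function(a, b) {
  if (rf_is_zero(a)) return(b)
  if (rf_is_zero(b)) return(a)
  # common denominator: union of factors at max powers
  den <- a$den
  for (f in b$den) {
    hit <- FALSE
    for (i in seq_along(den)) if (den[[i]]$id == f$id) {
      den[[i]]$k <- max(den[[i]]$k, f$k); hit <- TRUE; break
    }
    if (!hit) den[[length(den) + 1L]] <- f
  }
  lift <- function(x) {
    num <- x$num
    for (f in den) {
      have <- 0L
      for (g in x$den) if (g$id == f$id) { have <- g$k; break }
      for (i in seq_len(f$k - have)) num <- mp_mul(num, f$f)
    }
    num
  }
  .rf_cancel(rf(mp_add(lift(a), lift(b)), den))
}

rf_sub <- function(a, b) rf_add(a, rf_neg(b))

rf_div <- function(a, b) {
  if (rf_is_zero(b)) stop("rational-function division by zero", call. = FALSE)
  # 1/b = (prod of b's den factors) / b$num
  pr <- .rf_den_factor(b$num)
  inv_num <- mp_const(qn_div(c(1, 1), pr$scale))
  for (f in b$den) for (i in seq_len(f$k)) inv_num <- mp_mul(inv_num, f$f)
  inv_den <- if (length(pr$f$terms) == 1L && length(pr$f$terms[[1]]$e) == 0L) {
    q <- pr$f$terms[[1]]$q
    inv_num <- mp_scale(inv_num, qn_div(c(1, 1), q))
    list()
  } else list(list(f = pr$f, k = 1L, id = pr$id))
  rf_mul(a, rf(inv_num, inv_den))
}

rf_eval <- function(x, env) {
  v <- mp_eval(x$num, env)
  for (f in x$den) v <- v / mp_eval(f$f, env)^f$k
  v
}

rf_format <- function(x) {
  if (rf_is_zero(x)) return("0")
  if (length(x$den) == 0L) return(mp_format(x$num))
  dn <- paste(vapply(x$den, function(f) {
    base <- paste0("(", mp_format(f$f), ")")
    if (f$k > 1L) paste0(base, "^", f$k) else base
  }, ""), collapse = "*")
  paste0("(", mp_format(x$num), ") / (", dn, ")")
}

## ---- polynomials in state variables with rational-function coefficients --

pv_zero <- function() structure(list(terms = list()), class = "cmt_pvf")

pv_const <- function(cf) {
  if (rf_is_zero(cf)) return(pv_zero())
  structure(list(terms = structure(list(list(e = integer(0), c = cf)),
                                   names = "1")), class = "cmt_pvf")
}

pv_sym <- function(name, cf = NULL, pow = 1L) {
  if (is.null(cf)) cf <- rf_const(qn(1))
  if (rf_is_zero(cf)) return(pv_zero())
  e <- structure(as.integer(pow), names = name)
  structure(list(terms = structure(list(list(e = e, c = cf)),
                                   names = .mp_key(e))), class = "cmt_pvf")
}

pv_is_zero <- function(p) length(p$terms) == 0L

pv_add <- function(a, b) {
  terms <- a$terms
  for (k in names(b$terms)) {
    tb <- b$terms[[k]]
    if (is.null(terms[[k]])) {
      terms[[k]] <- tb
    } else {
      s <- rf_add(terms[[k]]$c, tb$c)
      if (rf_is_zero(s)) terms[[k]] <- NULL else terms[[k]]$c <- s
    }
  }
  structure(list(terms = terms), class = "cmt_pvf")
}

pv_neg <- function(a) {
  for (k in names(a$terms)) a$terms[[k]]$c <- rf_neg(a$terms[[k]]$c)
  a
}
pv_sub <- function(a, b) pv_add(a, pv_neg(b))

pv_mul <- function(a, b) {
  out <- pv_zero()
  for (ta in a$terms) for (tb in b$terms) {
    e <- .mp_exp_mul(ta$e, tb$e)
    k <- .mp_key(e)
    cf <- rf_mul(ta$c, tb$c)
    if (rf_is_zero(cf)) next
    cur <- out$terms[[k]]
    if (is.null(cur)) {
      out$terms[[k]] <- list(e = e, c = cf)
    } else {
      s <- rf_add(cur$c, cf)
      if (rf_is_zero(s)) out$terms[[k]] <- NULL else out$terms[[k]]$c <- s
    }
  }
  out
}

pv_scale <- function(a, cf) {
  if (rf_is_zero(cf)) return(pv_zero())
  for (k in names(a$terms)) a$terms[[k]]$c <- rf_mul(a$terms[[k]]$c, cf)
  a
}

# product truncated on the fly: term pairs whose combined degree in
# `tvars` exceeds maxdeg are never formed (the expensive part of a
# coefficient product is the rational-function arithmetic, so skipping
# doomed pairs matters)
pv_mul_trunc <- function(a, b, tvars, maxdeg) {
  dg <- function(t) sum(t$e[names(t$e) %in% tvars])
  out <- pv_zero()
  for (ta in a$terms) {
    da <- dg(ta)
    if (da > maxdeg) next
    for (tb in b$terms) {
      if (da + dg(tb) > maxdeg) next
      e <- .mp_exp_mul(ta$e, tb$e)
      k <- .mp_key(e)
      cf <- rf_mul(ta$c, tb$c)
      if (rf_is_zero(cf)) next
      cur <- out$terms[[k]]
      if (is.null(cur)) {
        out$terms[[k]] <- list(e = e, c = cf)
      } else {
        s <- rf_add(cur$c, cf)
        if (rf_is_zero(s)) out$terms[[k]] <- NULL else out$terms[[k]]$c <- s
      }
    }
  }
  out
}

# substitution with on-the-fly truncation (see pv_mul_trunc)
pv_subst_trunc <- function(p, var, repl, tvars, maxdeg) {
  out <- pv_zero()
  pows <- list()
  for (t in p$terms) {
    d <- if (var %in% names(t$e)) t$e[[var]] else 0L
    rest <- t$e[names(t$e) != var]
    base <- structure(list(terms = structure(
      list(list(e = rest, c = t$c)), names = .mp_key(rest))),
      class = "cmt_pvf")
    if (d == 0L) {
      out <- pv_add(out, pv_trunc(base, tvars, maxdeg))
      next
    }
    key <- as.character(d)
    if (is.null(pows[[key]])) {
      pw <- pv_trunc(repl, tvars, maxdeg)
      for (i in seq_len(d - 1L)) pw <- pv_mul_trunc(pw, repl, tvars, maxdeg)
      pows[[key]] <- pw
    }
    out <- pv_add(out, pv_mul_trunc(base, pows[[key]], tvars, maxdeg))
  }
  out
}

# substitute state variable `var` by polynomial `repl`
pv_subst <- function(p, var, repl) {
  out <- pv_zero()
  pows <- list()                      # cached powers of repl
  for (t in p$terms) {
    d <- if (var %in% names(t$e)) t$e[[var]] else 0L
    rest <- t$e[names(t$e) != var]
    base <- structure(list(terms = structure(
      list(list(e = rest, c = t$c)), names = .mp_key(rest))),
      class = "cmt_pvf")
    if (d == 0L) { out <- pv_add(out, base); next }
    key <- as.character(d)
    if (is.null(pows[[key]])) {
      pw <- repl
      for (i in seq_len(d - 1L)) pw <- pv_mul(pw, repl)
      pows[[key]] <- pw
    }
    out <- pv_add(out, pv_mul(base, pows[[key]]))
  }
  out
}

# drop terms whose total degree in `vars` exceeds maxdeg
pv_trunc <- function(p, vars, maxdeg) {
  keep <- list()
  for (k in names(p$terms)) {
    t <- p$terms[[k]]
    d <- sum(t$e[names(t$e) %in% vars])
    if (d <= maxdeg) keep[[k]] <- t
  }
  structure(list(terms = keep), class = "cmt_pvf")
}

pv_deriv <- function(p, var) {
  out <- pv_zero()
  for (t in p$terms) {
    if (!(var %in% names(t$e))) next
    d <- t$e[[var]]
    e <- t$e
    if (d == 1L) e <- e[names(e) != var] else e[[var]] <- d - 1L
    term <- structure(list(terms = structure(
      list(list(e = e, c = rf_mul(t$c, rf_const(qn(d))))),
      names = .mp_key(e))), class = "cmt_pvf")
    out <- pv_add(out, term)
  }
  out
}

# coefficient of the monomial with exponents `e_target` (named integer
# vector) over the variables named in it; returns a cmt_pvf in the
# remaining state variables.
pv_coeff <- function(p, e_target) {
  vars <- names(e_target)
  out <- pv_zero()
  for (t in p$terms) {
    e_in <- structure(integer(length(vars)), names = vars)
    hit <- names(t$e)[names(t$e) %in% vars]
    e_in[hit] <- t$e[hit]
    if (!all(e_in == e_target)) next
    rest <- t$e[!(names(t$e) %in% vars)]
    term <- structure(list(terms = structure(
      list(list(e = rest, c = t$c)), names = .mp_key(rest))),
      class = "cmt_pvf")
    out <- pv_add(out, term)
  }
  out
}

pv_eval <- function(p, env) {
  tot <- 0
  for (t in p$terms) {
    v <- rf_eval(t$c, env)
    for (nm in names(t$e)) v <- v * env[[nm]]^t$e[[nm]]
    tot <- tot + v
  }
  tot
}

pv_format <- function(p) {
  if (pv_is_zero(p)) return("0")
  ks <- sort(names(p$terms))
  paste(vapply(ks, function(k) {
    t <- p$terms[[k]]
    mono <- if (length(t$e) == 0L) "1" else
      paste(vapply(seq_along(t$e), function(i)
        if (t$e[i] == 1L) names(t$e)[i] else
          paste0(names(t$e)[i], "^", t$e[i]), ""), collapse = "*")
    paste0("[", rf_format(t$c), "]*", mono)
  }, ""), collapse = " + ")
}

# solve a linear system over the rational-function field:
# eqs: list of cmt_pvf, each linear in the unknown state variables
# `unknowns`; every equation must reduce to 0.  Returns named list of
# cmt_rfun solutions.
pv_solve_linear <- function(eqs, unknowns) {
  m <- length(eqs); n <- length(unknowns)
  A <- vector("list", m)
  bvec <- vector("list", m)
  for (i in seq_len(m)) {
    row <- vector("list", n)
    for (j in seq_len(n)) {
      cf <- pv_coeff(eqs[[i]], structure(1L, names = unknowns[j]))
      if (!pv_is_zero(cf)) {
        if (length(cf$terms) != 1L || length(cf$terms[[1]]$e) != 0L)
          stop("equation not linear in ", unknowns[j], call. = FALSE)
        row[[j]] <- cf$terms[[1]]$c
      } else row[[j]] <- rf(mp_zero())
    }
    A[[i]] <- row
    # constant part = equation with all unknowns set to zero
    cst <- eqs[[i]]
    for (u in unknowns) cst <- pv_subst(cst, u, pv_zero())
    if (pv_is_zero(cst)) {
      bvec[[i]] <- rf(mp_zero())
    } else {
      if (length(cst$terms) != 1L || length(cst$terms[[1]]$e) != 0L)
        stop("nonlinear residual in linear solve", call. = FALSE)
      bvec[[i]] <- cst$terms[[1]]$c
    }
  }
  # Gaussian elimination (solve A x = -b)
  x <- structure(vector("list", n), names = unknowns)
  used <- rep(FALSE, m)
  for (j in seq_len(n)) {
    piv <- NA_integer_
    for (i in seq_len(m)) if (!used[i] && !rf_is_zero(A[[i]][[j]])) { piv <- i; break }
    if (is.na(piv))
      stop("singular invariance system at unknown ", unknowns[j],
           " (non-hyperbolic fast direction)", call. = FALSE)
    used[piv] <- TRUE
    pv <- A[[piv]][[j]]
    for (i in seq_len(m)) {
      if (i == piv || rf_is_zero(A[[i]][[j]])) next
      f <- rf_div(A[[i]][[j]], pv)
      for (jj in seq_len(n))
        A[[i]][[jj]] <- rf_sub(A[[i]][[jj]], rf_mul(f, A[[piv]][[jj]]))
      bvec[[i]] <- rf_sub(bvec[[i]], rf_mul(f, bvec[[piv]]))
    }
  }
  # back out solutions: each used row now has a single nonzero coefficient
  for (i in seq_len(m)) {
    nz <- which(vapply(A[[i]], Negate(rf_is_zero), TRUE))
    if (length(nz) == 0L) {
      if (!rf_is_zero(bvec[[i]]))
        stop("inconsistent invariance system", call. = FALSE)
      next
    }
    if (length(nz) > 1L) stop("elimination failed", call. = FALSE)
    x[[unknowns[nz]]] <- rf_neg(rf_div(bvec[[i]], A[[i]][[nz]]))
  }
  for (j in seq_len(n)) if (is.null(x[[j]])) x[[j]] <- rf(mp_zero())
  x
}
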