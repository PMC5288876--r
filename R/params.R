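# Parameter containers for the assembly model.
#
# The model tracks three monomer pools: X (ATP/GTP-bound, assembly-active),
# Y (ADP/GDP-bound, incorporated at the oligomer tip) and Z (released
# ADP/GDP-bound).  The oligomer concentration W and the total monomer
# concentration M are held constant.  Microscopic rate/diffusion constants
# are collapsed into the lumped coefficients that the two-dimensional
# fluctuation system actually uses:
#   D1 = k1*DX*W   (attachment, diffusion-limited)
#   D2 = k2*DY     (release, diffusion-limited)
#   a  = k1*DX*W*alpha,  b = k1*DX*W*beta   (diffusion feedback on dx/dt)
#   c  = k2*gamma                           (diffusion feedback on dz/dt)
#   d  = coefficient of the x*z cross term in dz/dt (simulation variant)
#   k  = k3        (direct X -> Z conversion)
#   p  = k0*P      (cofactor exchange supply, the bifurcation parameter)

.lumped_keys <- c("D1", "D2", "a", "b", "c", "d", "k", "p", "M", "W")
.micro_keys  <- c("k0", "k1", "k2", "k3", "DX", "DY", "DW", "P", "W", "M",
                  "alpha", "beta", "gamma", "delta")

.check_nonneg <- function(vals, keys) {
  for (key in keys) {
    v <- vals[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", key, "' must be a finite numeric scalar",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", key, "' must be nonnegative (got ", v, ")",
           call. = FALSE)
  }
}

#' Lumped kinetic parameters
#'
#' Construct the lumped parameter set of the fluctuation model.  All
#' parameters must be nonnegative and `M`, `W` strictly positive.
#'
#' @param D1 attachment coefficient `k1*DX*W` (1/time)
#' @param D2 release coefficient `k2*DY` (1/time)
#' @param a,b diffusion-feedback coefficients on `x` and `z` in `dx/dt`
#' @param c diffusion-feedback coefficient in `dz/dt`
#' @param d coefficient of the `x*z` cross term in `dz/dt` (simulation
#'   variant of the feedback; 0 in the canonical parameter sets)
#' @param k direct X to Z conversion rate (1/time)
#' @param p cofactor supply `k0*P`; the bifurcation parameter
#' @param M total monomer concentration (constant)
#' @param W oligomer concentration (constant)
#' @return an object of class `cmt_params`
#' @seealso [preset_params()], [lump_parameters()], [steady_state()]
#' @export
#' @examples
#' pr <- preset_params("fig2_code", p = 0.01)
#' steady_state(pr)
model_params <- function(D1, D2, a = 0, b = 0, c = 0, d = 0, k = 0,
                         p = 0, M, W = 1) {
  vals <- list(D1 = D1, D2 = D2, a = a, b = b, c = c, d = d, k = k,
               p = p, M = M, W = W)
  .check_nonneg(vals, .lumped_keys)
  if (M <= 0) stop("total monomer concentration M must be > 0", call. = FALSE)
  if (W <= 0) stop("oligomer concentration W must be > 0", call. = FALSE)
  structure(vals, class = "cmt_params")
}

#' Microscopic rate and diffusion constants
#'
#' The microscopic parameterisation behind [model_params()]: exchange rate
#' `k0`, diffusion-proportionality coefficients `k1`, `k2`, direct
#' conversion `k3`, diffusion coefficients `DX`, `DY`, `DW`, cofactor
#' concentration `P`, and the diffusion-fluctuation coefficients
#' `alpha`, `beta` (feedback on `DX`) and `gamma`, `delta` (feedback on
#' `DZ`).  The model assumes oligomer diffusion is slow (`DW` much smaller
#' than `DX` and `DY`); this is advisory and produces a warning, not an
#' error, when violated.
#'
#' @param k0 cofactor-exchange rate (1/(conc*time))
#' @param k1,k2 diffusion-proportionality coefficients
#' @param k3 direct X to Z conversion rate (1/time)
#' @param DX,DY,DW diffusion coefficients (area/time)
#' @param P active-cofactor concentration
#' @param W oligomer concentration (constant)
#' @param M total monomer concentration
#' @param alpha,beta,gamma,delta diffusion-fluctuation coefficients
#' @return an object of class `cmt_micro`
#' @export
micro_params <- function(k0 = 0, k1 = 0, k2 = 0, k3 = 0, DX = 0, DY = 0,
                         DW = 0, P = 0, W = 1, M = 1, alpha = 0, beta = 0,
                         gamma = 0, delta = 0) {
  vals <- list(k0 = k0, k1 = k1, k2 = k2, k3 = k3, DX = DX, DY = DY,
               DW = DW, P = P, W = W, M = M, alpha = alpha, beta = beta,
               gamma = gamma, delta = delta)
  .check_nonneg(vals, .micro_keys)
  if (M <= 0) stop("total monomer concentration M must be > 0", call. = FALSE)
  if (W <= 0) stop("oligomer concentration W must be > 0", call. = FALSE)
  if (DW > 0 && (DW >= DX || DW >= DY))
    warning("model assumes oligomer diffusion DW << DX and DW << DY",
            call. = FALSE)
  structure(vals, class = "cmt_micro")
}

#' Collapse microscopic constants into lumped model parameters
#'
#' Applies the lumping rules `D1 = k1*DX*W`, `D2 = k2*DY`,
#' `a = k1*DX*W*alpha`, `b = k1*DX*W*beta`, `c = k2*gamma`, `k = k3`,
#' `p = k0*P`.  The `delta` feedback on the diffusion of Z is accepted in
#' the microscopic set but does not enter the lumped dynamics (the model
#' treats that term as negligible), and the `d` cross-term coefficient of
#' the simulation variant has no microscopic counterpart, so it is 0.
#'
#' Note the lumping is the interface the numerical work uses verbatim; a
#' direct expansion of the microscopic fluctuation equations would attach
#' `k1*W*alpha` (without `DX`) to the quadratic term, so the microscopic
#' and lumped routes agree exactly only on the linear coefficients.  The
#' lumped set is authoritative throughout.
#'
#' @param micro a `cmt_micro` object
#' @return a `cmt_params` object
#' @export
lump_parameters <- function(micro) {
  stopifnot(inherits(micro, "cmt_micro"))
  model_params(D1 = micro$k1 * micro$DX * micro$W,
               D2 = micro$k2 * micro$DY,
               a  = micro$k1 * micro$DX * micro$W * micro$alpha,
               b  = micro$k1 * micro$DX * micro$W * micro$beta,
               c  = micro$k2 * micro$gamma,
               d  = 0,
               k  = micro$k3,
               p  = micro$k0 * micro$P,
               M  = micro$M, W = micro$W)
}

#' Named parameter presets
#'
#' Two canonical parameter sets ship with the package: `"fig2_code"`, the
#' set used by the published simulation code (the only set whose critical
#' point and trajectory regimes are reported), and `"text_2017"`, the
#' slightly different set listed in the accompanying text (b = 150,
#' c = 0).  Presets are constructed afresh on every call and are therefore
#' immutable.
#'
#' @param name preset name, `"fig2_code"` or `"text_2017"`
#' @param p optional cofactor supply to install in the returned set
#' @return a `cmt_params` object
#' @export
preset_params <- function(name = c("fig2_code", "text_2017"), p = NULL) {
  name <- match.arg(name)
  pr <- switch(name,
    fig2_code = model_params(D1 = 0.28, D2 = 0.012061855670103093,
                             a = 150, b = 156, c = 0.1, d = 0,
                             k = 0.005, p = 0, M = 0.1, W = 1),
    text_2017 = model_params(D1 = 0.28, D2 = 0.012, a = 150, b = 150,
                             c = 0, d = 0, k = 0.005, p = 0, M = 0.1,
                             W = 1))
  if (!is.null(p)) pr <- set_p(pr, p)
  attr(pr, "preset") <- name
  pr
}

#' @export
print.cmt_params <- function(x, ...) {
  cat("Lumped assembly-model parameters\n")
  if (!is.null(attr(x, "preset")))
    cat("  preset:", attr(x, "preset"), "\n")
  cat(paste0("  ", format(.lumped_keys, width = 3), " = ",
             vapply(.lumped_keys, function(k) format(x[[k]], digits = 12),
                    ""), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.cmt_micro <- function(x, ...) {
  cat("Microscopic assembly-model parameters\n")
  cat(paste0("  ", format(.micro_keys, width = 6), " = ",
             vapply(.micro_keys, function(k) format(x[[k]], digits = 12),
                    ""), collapse = "\n"), "\n")
  invisible(x)
}

# replace the cofactor supply p, preserving validation
set_p <- function(params, p) {
  stopifnot(inherits(params, "cmt_params"))
  preset <- attr(params, "preset")
  vals <- unclass(params)
  attributes(vals) <- list(names = names(vals))
  vals$p <- p
  out <- do.call(model_params, vals)
  attr(out, "preset") <- preset
  out
}

#' Read or write parameter sets as flat JSON documents
#'
#' Parameter files are flat key-value JSON objects using the exact symbol
#' names `D1, D2, a, b, c, d, k, p, M, W` (lumped schema) or
#' `k0, k1, k2, k3, DX, DY, DW, P, W, M, alpha, beta, gamma, delta`
#' (microscopic schema).  The schema is detected from the keys present;
#' unknown keys are rejected.
#'
#' @param path file path
#' @return `read_params()` returns a `cmt_params` or `cmt_micro` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- names(vals)
  if (all(keys %in% .lumped_keys)) {
    do.call(model_params, as.list(vals))
  } else if (all(keys %in% .micro_keys)) {
    do.call(micro_params, as.list(vals))
  } else {
    bad <- setdiff(keys, union(.lumped_keys, .micro_keys))
    stop("unknown parameter keys in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' @rdname read_params
#' @param params a `cmt_params` or `cmt_micro` object
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cmt_params") || inherits(params, "cmt_micro"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
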