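#' Interaction model for the density functional
#'
#' Defines the per-point interaction energy density w of the filtered
#' species densities.  The default is the standard chi/kappa mixing
#' functional of hybrid particle-field models,
#'
#'   w = (1 / 2 phi0) ( sum_kl chi_kl phit_k phit_l
#'                      + kappa^-1 (sum_k phit_k - phi0)^2 ),
#'
#' where chi_kl is the Flory-Huggins mixing parameter between species k and
#' l (kJ/mol), kappa^-1 the incompressibility penalty (kJ/mol) and phi0 the
#' average number density (nm^-3).  A custom local functional may be given
#' as an R expression in variables named `phi_<species>` (plus the model
#' constants `phi0`, `kappa_inv`); its derivatives are obtained by symbolic
#' differentiation.
#'
#' @param chi K x K symmetric matrix of mixing parameters (kJ/mol);
#'   dimnames, when present, must match `species`.
#' @param kappa_inv incompressibility parameter kappa^-1 (kJ/mol).  The
#'   conventional value is 7.45 * R * T.
#' @param sigma Gaussian filter width (nm), > 0.
#' @param phi0 average number density (nm^-3), > 0.
#' @param species character vector of species names (defines the index
#'   order of `chi`).
#' @param w optional custom functional: an expression or quote()d call in
#'   `phi_<species>` variables, e.g.
#'   `quote(0.5 * kappa_inv / phi0 * (phi_A - phi0)^2)`.
#' @return An object of class `interaction_model`.
#' @export
interaction_model <- function(chi = NULL, kappa_inv, sigma, phi0,
                              species = NULL, w = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.numeric(phi0) || phi0 <= 0) stop("phi0 must be > 0")
  if (is.null(species)) {
    species <- if (!is.null(chi) && !is.null(colnames(chi))) colnames(chi)
               else paste0("S", seq_len(max(1L, nrow(chi %||% matrix(0, 1, 1)))))
  }
  k <- length(species)
  if (is.null(chi)) chi <- matrix(0, k, k)
  chi <- as.matrix(chi)
  if (!all(dim(chi) == c(k, k))) stop("chi must be K x K for K species")
  if (max(abs(chi - t(chi))) > 1e-10) stop("chi must be symmetric")
  dimnames(chi) <- list(species, species)
  model <- structure(list(chi = chi, kappa_inv = as.numeric(kappa_inv),
                          sigma = as.numeric(sigma), phi0 = as.numeric(phi0),
                          species = species, w = w),
                     class = "interaction_model")
  if (!is.null(w)) model$dw <- .functional_derivatives(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symbolic derivatives dw/dphi_k of a custom functional
.functional_derivatives <- function(model) {
  vars <- paste0("phi_", model$species)
  expr <- model$w
  if (is.expression(expr)) expr <- expr[[1]]
  lapply(vars, function(v) {
    d <- tryCatch(stats::D(expr, v),
                  error = function(e)
                    stop("custom functional is not differentiable with ",
                         "respect to ", v, ": ", conditionMessage(e)))
    d
  })
}

# evaluate w (and optionally each dw/dphi_k) on grids
.eval_functional <- function(model, phit_list, what = c("w", "dw")) {
  what <- match.arg(what)
  env <- new.env(parent = baseenv())
  for (k in seq_along(model$species))
    assign(paste0("phi_", model$species[k]), phit_list[[k]], envir = env)
  assign("phi0", model$phi0, envir = env)
  assign("kappa_inv", model$kappa_inv, envir = env)
  if (what == "w") {
    expr <- model$w
    if (is.expression(expr)) expr <- expr[[1]]
    return(eval(expr, env))
  }
  lapply(model$dw, function(d) {
    v <- eval(d, env)
    if (length(v) == 1L) v + 0 * phit_list[[1]] else v
  })
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("interaction_model:", length(x$species), "species (",
      paste(x$species, collapse = ", "), ")\n")
  cat("  sigma =", x$sigma, "nm, kappa_inv =", signif(x$kappa_inv, 5),
      "kJ/mol, phi0 =", signif(x$phi0, 5), "nm^-3\n")
  if (!is.null(x$w)) cat("  custom functional:", deparse(x$w), "\n")
  invisible(x)
}
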