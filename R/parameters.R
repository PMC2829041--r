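#' Model parameters for the leading-edge adhesion/protrusion model
#'
#' Constructs and validates the full parameter set of the model. All rate
#' constants are first-order with units of 1/min; gains (`E_s`, `I_n`),
#' removal coefficient (`C_s`), basal activities (`p0`, `v0`), the velocity
#' half-saturation `K_v` and the ratios `K_i = k_a_i / k_d_i` are
#' dimensionless; `D_r` is in um^2/min.
#'
#' @param k_ecm ECM coupling parameter (1/min). Maps, not necessarily
#'   linearly, to extracellular-matrix density; multiplies the
#'   velocity-proportional nascent-adhesion formation rate.
#' @param E_s Gain of the myosin feedback on adhesion maturation,
#'   `f(m) = 1 + E_s * m`. `E_s = 0` switches the feedback off.
#' @param I_n Gain of protrusion inhibition by stable adhesions,
#'   `g(s) = 1 + I_n * s`. `I_n = 0` switches the inhibition off.
#' @param C_s Convective-removal coefficient: stable-adhesion loss is
#'   `k_d_s * (1 + C_s * v) * s`, so a protruding edge outruns its stable
#'   adhesions. Fixed at 10 in the base case.
#' @param k_d_n Nascent-adhesion turnover rate constant (1/min); realized
#'   turnover is `k_d_n * v * n`, coupled to protrusion.
#' @param p0 Basal paxillin phosphorylation activity; lets `x`, `r`, `p`
#'   grow from an all-zero start once nascent adhesions exist.
#' @param v0 Basal (Rac-independent) protrusion drive in the velocity law;
#'   lets `n` grow from an all-zero start.
#' @param K_v Half-saturation of the velocity response to active Rac.
#' @param D_r Diffusion coefficient of active Rac (um^2/min); used only by
#'   the spatial simulator.
#' @param rate_constants Named list over species `s`, `m`, `x`, `r`, `p`,
#'   each a list/vector with elements `k_a` and `k_d` (1/min):
#'   maturation/recruitment/activation and disassembly/deactivation rate
#'   constants.
#'
#' @return An object of class `adhesion_params`: a validated list with the
#'   above fields plus `K_ratios` (`K_i = k_a_i/k_d_i` per species).
#' @examples
#' p <- base_case_params()
#' p$K_ratios[["r"]]   # K_r = 10
#' @seealso [base_case_params()], [update_params()], [load_params()]
#' @export
adhesion_params <- function(k_ecm = 0.1, E_s = 0, I_n = 0, C_s = 10,
                            k_d_n = 0.05, p0 = 5e-3, v0 = 1e-2, K_v = 0.2,
                            D_r = 15,
                            rate_constants = list(
                              s = c(k_a = 0.005, k_d = 0.01),
                              m = c(k_a = 20,   k_d = 2),
                              x = c(k_a = 15,   k_d = 5),
                              r = c(k_a = 40,   k_d = 4),
                              p = c(k_a = 18,   k_d = 4))) {
  rc <- lapply(rate_constants, function(z) {
    z <- unlist(z)
    if (!all(c("k_a", "k_d") %in% names(z)))
      stop("each rate_constants entry needs named elements k_a and k_d")
    c(k_a = unname(z[["k_a"]]), k_d = unname(z[["k_d"]]))
  })
  need <- c("s", "m", "x", "r", "p")
  if (!setequal(names(rc), need))
    stop("rate_constants must have exactly the species: ",
         paste(need, collapse = ", "))
  rc <- rc[need]
  obj <- structure(list(
    k_ecm = k_ecm, E_s = E_s, I_n = I_n, C_s = C_s, k_d_n = k_d_n,
    p0 = p0, v0 = v0, K_v = K_v, D_r = D_r,
    rate_constants = rc,
    K_ratios = vapply(rc, function(z) z[["k_a"]] / z[["k_d"]], numeric(1))),
    class = "adhesion_params")
  validate_params(obj)
  obj
}

validate_params <- function(p) {
  scal <- c(k_ecm = p$k_ecm, E_s = p$E_s, I_n = p$I_n, C_s = p$C_s,
            k_d_n = p$k_d_n, p0 = p$p0, v0 = p$v0, K_v = p$K_v, D_r = p$D_r)
  if (any(!is.finite(scal)))
    stop("non-finite parameter: ", paste(names(scal)[!is.finite(scal)], collapse = ", "))
  if (any(scal < 0))
    stop("negative parameter: ", paste(names(scal)[scal < 0], collapse = ", "))
  for (sp in names(p$rate_constants)) {
    z <- p$rate_constants[[sp]]
    if (any(!is.finite(z)) || any(z < 0))
      stop("invalid rate constants for species ", sp)
    if (z[["k_d"]] > 0) {
      K <- z[["k_a"]] / z[["k_d"]]
      if (abs(p$K_ratios[[sp]] - K) > 1e-12 * max(1, abs(K)))
        stop("K_ratios inconsistent with rate constants for species ", sp)
    }
  }
  invisible(p)
}

#' Base-case parameter set
#'
#' Loads the parameter file shipped with the package
#' (`inst/extdata/base_case.yaml`), optionally applying overrides. The base
#' case places the model, at `E_s = I_n = 0`, in its bistable regime at
#' `k_ecm = 0.1` 1/min, monostable low at 0.03 and monostable high at 0.3.
#'
#' @param ... Named overrides, e.g. `base_case_params(k_ecm = 0.3, E_s = 10)`.
#' @return An `adhesion_params` object.
#' @export
base_case_params <- function(...) {
  path <- system.file("extdata", "base_case.yaml", package = "adhesim")
  update_params(load_params(path), ...)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named top-level fields replaced, or
#' rate constants replaced via names like `k_a_s`, `k_d_r`.
#'
#' @param params An `adhesion_params` object.
#' @param ... Named replacements. Unknown names are an error.
#' @return A new `adhesion_params` object.
#' @export
update_params <- function(params, ...) {
  ov <- list(...)
  if (!length(ov)) return(params)
  if (is.null(names(ov)) || any(names(ov) == ""))
    stop("all overrides must be named")
  raw <- unclass(params)
  for (nm in names(ov)) {
    if (nm %in% c("k_ecm", "E_s", "I_n", "C_s", "k_d_n", "p0", "v0", "K_v", "D_r")) {
      raw[[nm]] <- ov[[nm]]
    } else if (grepl("^k_[ad]_[smxrp]$", nm)) {
      sp <- substr(nm, 5, 5)
      which <- if (substr(nm, 3, 3) == "a") "k_a" else "k_d"
      raw$rate_constants[[sp]][[which]] <- ov[[nm]]
    } else stop("unknown parameter: ", nm)
  }
  adhesion_params(k_ecm = raw$k_ecm, E_s = raw$E_s, I_n = raw$I_n,
                  C_s = raw$C_s, k_d_n = raw$k_d_n, p0 = raw$p0, v0 = raw$v0,
                  K_v = raw$K_v, D_r = raw$D_r,
                  rate_constants = raw$rate_constants)
}

#' Read a parameter file (YAML or JSON)
#'
#' Keys must match [adhesion_params()] argument names exactly; unknown keys
#' are rejected by name.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return An `adhesion_params` object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  allowed <- names(formals(adhesion_params))
  bad <- setdiff(names(lst), allowed)
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  do.call(adhesion_params, lst)
}

#' Write a parameter file
#'
#' @param params An `adhesion_params` object.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  lst <- unclass(params)
  lst$K_ratios <- NULL
  lst$rate_constants <- lapply(lst$rate_constants, as.list)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

#' @export
print.adhesion_params <- function(x, ...) {
  cat("Leading-edge adhesion/protrusion model parameters\n")
  cat(sprintf("  k_ecm = %g /min, E_s = %g, I_n = %g, C_s = %g\n",
              x$k_ecm, x$E_s, x$I_n, x$C_s))
  cat(sprintf("  k_d_n = %g /min, p0 = %g, v0 = %g, K_v = %g, D_r = %g um^2/min\n",
              x$k_d_n, x$p0, x$v0, x$K_v, x$D_r))
  for (sp in names(x$rate_constants))
    cat(sprintf("  %s: k_a = %g, k_d = %g /min (K_%s = %g)\n", sp,
                x$rate_constants[[sp]][["k_a"]],
                x$rate_constants[[sp]][["k_d"]], sp, x$K_ratios[[sp]]))
  invisible(x)
}

# internal: flatten to the numeric vector consumed by the C++ engines and
# the closed-form helpers (ordering is part of the C++ contract)
param_vector <- function(p) {
  c(k_ecm = p$k_ecm, E_s = p$E_s, I_n = p$I_n, C_s = p$C_s,
    k_d_n = p$k_d_n, p0 = p$p0, v0 = p$v0, K_v = p$K_v,
    k_a_s = p$rate_constants$s[["k_a"]], k_d_s = p$rate_constants$s[["k_d"]],
    k_a_m = p$rate_constants$m[["k_a"]], k_d_m = p$rate_constants$m[["k_d"]],
    k_a_x = p$rate_constants$x[["k_a"]], k_d_x = p$rate_constants$x[["k_d"]],
    k_a_r = p$rate_constants$r[["k_a"]], k_d_r = p$rate_constants$r[["k_d"]],
    k_a_p = p$rate_constants$p[["k_a"]], k_d_p = p$rate_constants$p[["k_d"]])
}
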