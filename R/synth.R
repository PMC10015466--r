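#' Noise specification for synthetic datasets
#'
#' Gaussian measurement noise, either relative (sigma is a fraction of the
#' noiseless value, emulating the ~1% reproducibility of relaxation-rate
#' measurements) or absolute (sigma in the units of the observable, e.g.
#' absorbance). A seed is mandatory whenever `sigma > 0` so that every
#' synthetic dataset is reproducible.
#'
#' @param kind `"relative-gaussian"` or `"absolute-gaussian"`
#' @param sigma noise level (>= 0)
#' @param seed integer seed (required when `sigma > 0`)
#' @return object of class `noise_spec`
#' @export
#' @examples
#' noise_spec("relative-gaussian", 0.01, seed = 7)
noise_spec <- function(kind = c("relative-gaussian", "absolute-gaussian"),
                       sigma = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma > 0 && is.null(seed))
    stop("a seed is mandatory for any sigma > 0")
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_spec")
}

# apply a noise spec to a noiseless vector, reproducibly
.apply_noise <- function(x, noise) {
  if (is.null(noise) || noise$sigma == 0) return(x)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  eps <- stats::rnorm(length(x))
  if (noise$kind == "relative-gaussian") x * (1 + noise$sigma * eps)
  else x + noise$sigma * eps
}

#' Synthetic multi-temperature NMRD profile
#'
#' Generates relaxivity datasets from the forward model [total_r1()] on
#' the standard measurement design: frequencies log-spaced over the
#' fast-field-cycling + high-field range, at the four temperatures of the
#' variable-temperature study. With `sigma = 0` the dataset equals the
#' forward model exactly.
#'
#' @param params a [relax_params()]
#' @param freqs proton Larmor frequencies, MHz (within 0.01-500)
#' @param temps temperatures, K
#' @param noise a [noise_spec()] (default: noiseless)
#' @return object of class `nmrd_dataset` (a data.frame with columns
#'   `freq_MHz`, `temperature_K`, `r1_mM_s`, `sigma`)
#' @export
#' @examples
#' d <- make_nmrd(tiron_relax_params("FeL2"),
#'                noise = noise_spec("relative-gaussian", 0.01, seed = 7))
#' head(d)
make_nmrd <- function(params,
                      freqs = 10^seq(log10(0.01), log10(500), length.out = 30),
                      temps = c(283, 288, 298, 310),
                      noise = noise_spec()) {
  if (any(freqs < 0.01 - 1e-12) || any(freqs > 500 + 1e-9))
    stop("frequencies must lie within 0.01-500 MHz")
  grid <- expand.grid(freq_MHz = freqs, temperature_K = temps,
                      KEEP.OUT.ATTRS = FALSE)
  r1 <- unlist(lapply(temps, function(Tu)
    total_r1(params, freqs, Tu)$r1))
  out <- data.frame(freq_MHz = grid$freq_MHz,
                    temperature_K = grid$temperature_K,
                    r1_mM_s = .apply_noise(r1, noise),
                    sigma = noise$sigma * if (noise$kind ==
                      "relative-gaussian") r1 else 1)
  class(out) <- c("nmrd_dataset", "data.frame")
  out
}

#' Synthetic variable-temperature 17O dataset
#'
#' Reduced transverse relaxation rates and shifts from [swift_connick()]
#' over the temperature range of the high-field 17O study.
#'
#' @param params an [o17_params()]
#' @param temps temperatures, K (within 278-350)
#' @param conc_mM complex concentration (metadata; reduced quantities are
#'   already normalized per mole fraction of bound water)
#' @param noise a [noise_spec()] applied to both observables
#' @return object of class `o17_dataset` (a data.frame with columns
#'   `temperature_K`, `R2r_s`, `dOmega_r_rad_s`), with attributes `B0` and
#'   `conc_mM`
#' @export
make_o17 <- function(params, temps = seq(278, 310, by = 4), conc_mM = 8,
                     noise = noise_spec()) {
  if (any(temps < 278 - 1e-9) || any(temps > 350 + 1e-9))
    stop("temperatures must lie within 278-350 K")
  sc <- swift_connick(params, temps)
  n <- length(temps)
  noisy <- .apply_noise(c(sc$R2r, sc$dOmega_r), noise)
  out <- data.frame(temperature_K = temps,
                    R2r_s = noisy[seq_len(n)],
                    dOmega_r_rad_s = noisy[n + seq_len(n)])
  attr(out, "B0") <- params$B0
  attr(out, "conc_mM") <- conc_mM
  class(out) <- c("o17_dataset", "data.frame")
  out
}

#' Synthetic spectrophotometric titration
#'
#' Absorbance-versus-pH dataset from the speciation model and a molar
#' absorptivity table, on the standard design (iron and a ~50-fold ligand
#' excess titrated over pH 2-10). The reported pH emulates the electrode
#' reading (`pH_read = pH_true + pA`).
#'
#' @param model a [species_model()]
#' @param eps molar absorptivity matrix (species x wavelength); default: a
#'   single-wavelength table for the three complexes
#' @param total_Fe,total_L totals, mol/L
#' @param pH true pH grid
#' @param noise a [noise_spec()] (absolute noise on absorbance)
#' @return a `titration_dataset` (see [simulate_observable()])
#' @export
make_titration <- function(model = tiron_constants(),
                           eps = matrix(c(1800, 2600, 2100), 3, 1,
                                        dimnames = list(c("FeL", "FeL2",
                                                          "FeL3"), "562")),
                           total_Fe = 0.19e-3, total_L = 9.1e-3,
                           pH = seq(2, 10, by = 0.25),
                           noise = noise_spec("absolute-gaussian", 0)) {
  td <- simulate_observable(model, "absorbance", total_Fe, total_L, pH,
                            eps = eps, absorbing = rownames(eps),
                            emulate_measured = TRUE)
  acols <- paste0("A", colnames(eps))
  A <- as.matrix(td$points[acols])
  A[] <- .apply_noise(as.vector(A), noise)
  td$points[acols] <- as.data.frame(A)
  td
}

#' Synthetic pseudo-first-order kinetic traces
#'
#' Mono-exponential absorbance decays with Gaussian noise, one trace per
#' rate constant.
#'
#' @param kd rate constant(s), s^-1 (one trace per element)
#' @param times sampling times, s
#' @param A0,Ap start and end absorbance
#' @param conditions optional list with `pH`, `CDTA_t`, `Fe_t`, `Tiron_t`
#'   recycled across traces
#' @param noise a [noise_spec()] (absolute noise on absorbance)
#' @return list of [kinetic_trace()] objects
#' @export
#' @examples
#' tr <- make_traces(kd = 8e-5, times = seq(0, 4e4, length.out = 40),
#'                   noise = noise_spec("absolute-gaussian", 0.002, seed = 3))
make_traces <- function(kd, times = seq(0, 4e4, length.out = 40),
                        A0 = 0.75, Ap = 0.10, conditions = list(),
                        noise = noise_spec("absolute-gaussian", 0)) {
  lapply(seq_along(kd), function(i) {
    A <- Ap + (A0 - Ap) * exp(-kd[i] * times)
    if (noise$sigma > 0) {
      # distinct but reproducible sub-seed per trace
      sub <- noise
      sub$seed <- noise$seed + i - 1L
      A <- .apply_noise(A, sub)
    }
    kinetic_trace(times, A,
                  pH = conditions$pH %||% NA,
                  CDTA_t = conditions$CDTA_t %||% NA,
                  Fe_t = conditions$Fe_t %||% NA,
                  Tiron_t = conditions$Tiron_t %||% NA)
  })
}
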