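#' Parameters of the two-phage chemostat model
#'
#' Constructs and validates the full parameter set of the delayed-lysis
#' chemostat model: a genetically modified (GM) phage that releases a
#' diffusible biofilm-degrading enzyme at lysis competes with a wild phage
#' for free bacteria, while a refuge population escapes infection and leaks
#' into the free state at an enzyme-dependent rate \code{h(E)} (see
#' [release_rate()]).
#'
#' Defaults are the model's standard parameterization. The enzyme-dependent
#' release function is stored as three named constants (`h_max`,
#' `release_shape`, `release_decay`) so that the baseline release rate
#' `h(0) = h_max / (1 + release_shape)` (0.01 per minute at defaults) is a
#' derived quantity, not an input.
#'
#' @param k Adsorption rate constant (mL per minute per particle).
#' @param w Washout/death rate of the continuous-flow environment (per
#'   minute); applied to free bacteria, phages, infected cells and enzyme.
#' @param b_G Burst size of the GM (enzyme-producing) phage (progeny per
#'   lysis).
#' @param b_W Burst size of the wild phage.
#' @param L Lysis time (latent period), minutes between infection and burst.
#' @param v Maximum bacterial growth rate (per minute).
#' @param Z Enzyme yield per GM lysis (enzyme units).
#' @param C Carrying capacity applied to total bacterial density B + R
#'   (cells per mL).
#' @param h_max Maximal refuge release rate (per minute).
#' @param release_shape Dimensionless shape constant of the release
#'   function.
#' @param release_decay Per-enzyme-unit multiplicative decay base of the
#'   release function; must lie strictly between 0 and 1.
#'
#' @return An object of class `phage_model_params`: a named list of the
#'   eleven validated constants.
#' @seealso [release_rate()], [derivative_field()], [burst_presets],
#'   [read_model_params()]
#' @examples
#' p <- model_params()
#' release_rate(0, p)   # baseline refuge release, 0.01 per minute
#' @export
model_params <- function(k = 1e-9, w = 0.05, b_G = 17, b_W = 20, L = 10,
                         v = 0.1, Z = 0.1, C = 5e9,
                         h_max = 0.2, release_shape = 19,
                         release_decay = 0.999997) {
  p <- list(k = k, w = w, b_G = b_G, b_W = b_W, L = L, v = v, Z = Z, C = C,
            h_max = h_max, release_shape = release_shape,
            release_decay = release_decay)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number")
  }
  # rate constants that may be switched off (k, Z) and burst sizes admit 0;
  # everything else must be strictly positive
  strict <- setdiff(names(p), c("b_G", "b_W", "k", "Z"))
  for (nm in strict)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  if (p$b_G < 0 || p$b_W < 0) stop("burst sizes must be >= 0")
  if (p$k < 0 || p$Z < 0) stop("'k' and 'Z' must be >= 0")
  if (p$release_decay >= 1)
    stop("'release_decay' must lie strictly between 0 and 1")
  structure(p, class = "phage_model_params")
}

#' @export
print.phage_model_params <- function(x, ...) {
  cat("Two-phage chemostat model parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Burst-size presets for the phage competition
#'
#' Three named configurations of the two burst sizes: the GM phage at a
#' disadvantage (17 vs 20), at an advantage (20 vs 17), or both phages
#' equal (20, 20). All other fitness components are shared.
#'
#' @format A named list of length-2 numeric vectors with elements `b_G`
#'   and `b_W`.
#' @seealso [apply_burst_preset()]
#' @export
burst_presets <- list(
  gm_disadvantaged = c(b_G = 17, b_W = 20),
  equal            = c(b_G = 20, b_W = 20),
  gm_advantaged    = c(b_G = 20, b_W = 17)
)

#' Apply a named burst-size preset to a parameter set
#'
#' @param params A [model_params()] object.
#' @param preset One of `"gm_disadvantaged"`, `"equal"`, `"gm_advantaged"`.
#' @return A new `phage_model_params` object with `b_G`, `b_W` replaced.
#' @export
apply_burst_preset <- function(params, preset = names(burst_presets)) {
  stopifnot(inherits(params, "phage_model_params"))
  preset <- match.arg(preset)
  b <- burst_presets[[preset]]
  params$b_G <- unname(b["b_G"])
  params$b_W <- unname(b["b_W"])
  params
}

#' Enzyme-dependent refuge release rate h(E)
#'
#' Rate (per minute) at which refuge bacteria move into the free,
#' phage-susceptible state, as a saturating function of ambient enzyme
#' density:
#' \deqn{h(E) = h_{max} / (1 + s \, d^{E})}
#' with shape constant \eqn{s} and decay base \eqn{d \in (0,1)}. At the
#' defaults the baseline is \eqn{h(0) = 0.2/20 = 0.01} per minute and the
#' rate saturates at \eqn{h_{max} = 0.2} as enzyme accumulates.
#'
#' @param E Enzyme density (enzyme units per mL); vectorized, must be
#'   non-negative.
#' @param params A [model_params()] object.
#' @return Release rate(s) per minute, strictly inside `(0, h_max)` and
#'   strictly increasing in `E`.
#' @examples
#' p <- model_params()
#' release_rate(c(0, 1e6, 1e7), p)
#' @export
release_rate <- function(E, params) {
  stopifnot(inherits(params, "phage_model_params"))
  if (!is.numeric(E) || any(!is.finite(E)) || any(E < 0))
    stop("'E' must be finite and non-negative")
  params$h_max / (1 + params$release_shape * params$release_decay^E)
}

.state_names <- c("B", "R", "P_G", "P_W", "I_G", "I_W", "E")

#' Construct a model state vector
#'
#' The seven dynamical variables of the model at one time point: free
#' bacteria `B`, refuge bacteria `R`, GM and wild phage `P_G`, `P_W`,
#' GM- and wild-infected bacteria `I_G`, `I_W` (infected, pre-lysis), and
#' enzyme density `E`. All densities are per mL and must be non-negative.
#'
#' @param B,R,P_G,P_W,I_G,I_W,E Non-negative densities.
#' @return A named numeric vector of length 7.
#' @export
state_vector <- function(B = 0, R = 0, P_G = 0, P_W = 0,
                         I_G = 0, I_W = 0, E = 0) {
  s <- c(B = B, R = R, P_G = P_G, P_W = P_W, I_G = I_G, I_W = I_W, E = E)
  validate_state(s)
  s
}

validate_state <- function(s, what = "state") {
  if (!is.numeric(s) || length(s) != 7L)
    stop(what, " must be a numeric vector of length 7")
  if (is.null(names(s)) || !all(names(s) == .state_names))
    stop(what, " must have components ", paste(.state_names, collapse = ", "))
  if (any(!is.finite(s))) stop(what, " has non-finite components")
  if (any(s < 0)) stop(what, " has negative components")
  invisible(s)
}

#' Write model parameters to a flat config file
#'
#' Serializes a parameter set as a two-column tab-separated file
#' (`parameter<TAB>value`) at full precision, so a round trip through
#' [read_model_params()] reproduces the parameters exactly.
#'
#' @param params A [model_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "phage_model_params"))
  lines <- c("parameter\tvalue",
             vapply(names(params), function(nm)
               sprintf("%s\t%.17g", nm, params[[nm]]), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read model parameters from a flat config file
#'
#' Reads a `parameter<TAB>value` file as written by [write_model_params()].
#' Unknown parameter names are rejected; omitted parameters take their
#' defaults. The packaged default config (see [default_params_file()])
#' reproduces the standard parameterization exactly.
#'
#' @param path Path to the config file.
#' @return A validated `phage_model_params` object.
#' @export
read_model_params <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric"))
  if (!identical(names(tab), c("parameter", "value")))
    stop("config file must have columns 'parameter' and 'value'")
  known <- names(formals(model_params))
  unknown <- setdiff(tab$parameter, known)
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(tab$parameter))
    stop("duplicated parameter(s) in config")
  do.call(model_params, setNames(as.list(tab$value), tab$parameter))
}

#' Path to the packaged default parameter config
#'
#' @return File path of the default parameter file shipped with the
#'   package (`extdata/default_model_params.tsv`).
#' @export
default_params_file <- function() {
  system.file("extdata", "default_model_params.tsv",
              package = "phagecommons", mustWork = TRUE)
}
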