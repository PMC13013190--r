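# Deterministic pharmacology: dose schedules, linear-compartment PK with an
# optional receptor-binding term, receptor occupancy, the K/PD chemotherapy
# kill rate with resistance, the Emax DDR-inhibitor effect, and
# oxygen-gradient scaling of local drug levels.

#' Compile a regimen specification into dose events
#'
#' Supported patterns: `"single"` (one dose), `"qnw"` with `n = 1, 2, 3 ...`
#' (e.g. `"q3w"` = every 504 h, the classic Q3W schedule), `"weekly"`
#' (alias of `"q1w"`), and `"fractionated"` (`days_per_week` consecutive
#' daily fractions per week for `weeks` weeks, e.g. 2.5 Gy on days 0-4 of
#' each of 6 weeks = 30 fractions).
#'
#' @param regimen a list with `modality` (one of `"pd1_antibody"`,
#'   `"docetaxel"`, `"ddri"`, `"radiation"`), `amount` (modality units:
#'   mg/kg, g, mg/m^2, Gy), `pattern`, `start_day` (default 0), and `n_doses`
#'   (for single/qnw/weekly) or `weeks` + `days_per_week` (for fractionated)
#' @return a data.frame with columns `time` (hours), `modality`, `amount`,
#'   sorted by time
#' @examples
#' build_schedule(list(modality = "pd1_antibody", amount = 2,
#'                     pattern = "q3w", start_day = 0, n_doses = 4))$time
#' @export
build_schedule <- function(regimen) {
  stopifnot(is.list(regimen), !is.null(regimen$modality), !is.null(regimen$amount))
  if (regimen$amount < 0) stop("dose amount must be nonnegative")
  start <- 24 * (regimen$start_day %||% 0)
  if (start < 0) stop("start_day must be nonnegative")
  pat <- tolower(regimen$pattern %||% "single")
  times <- if (pat == "single") {
    start
  } else if (grepl("^q[0-9]+w$", pat) || pat == "weekly") {
    nweeks <- if (pat == "weekly") 1L else as.integer(sub("^q([0-9]+)w$", "\\1", pat))
    n <- regimen$n_doses %||% stop("n_doses required for ", pat)
    start + (seq_len(n) - 1) * nweeks * 168
  } else if (pat == "fractionated") {
    weeks <- regimen$weeks %||% stop("weeks required for fractionated pattern")
    dpw <- regimen$days_per_week %||% 5L
    if (dpw > 7L) stop("days_per_week cannot exceed 7")
    grid <- expand.grid(d = seq_len(dpw) - 1L, w = seq_len(weeks) - 1L)
    start + (grid$w * 7 + grid$d) * 24
  } else stop("unknown dosing pattern: ", regimen$pattern)
  data.frame(time = sort(times), modality = regimen$modality,
             amount = regimen$amount, stringsAsFactors = FALSE)
}

.compile_schedule <- function(treatments) {
  if (!length(treatments)) {
    return(data.frame(time = numeric(0), modality = character(0),
                      amount = numeric(0), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, lapply(treatments, build_schedule))
  ev[order(ev$time), , drop = FALSE]
}

#' Integrate a linear compartmental PK model
#'
#' Solves a system of first-order transfer/elimination ODEs with bolus doses
#' added to the dosing compartment at event times, optionally extended with a
#' saturable drug-receptor binding term (the only nonlinearity):
#' `d(complex)/dt = kon * C_free * (r_tot - complex) - koff * complex`,
#' with the bound amount subtracted from the binding compartment.
#'
#' @param spec a list describing the model: `compartments` (character),
#'   `transfer` (data.frame with `from`, `to`, `rate` per hour),
#'   `elim` (named per-hour elimination rates), `dosing` (name of the dosing
#'   compartment), `volumes` (named, litres; default 1), and optionally
#'   `binding = list(compartment, complex, kon, koff, r_tot)` where `complex`
#'   names a compartment holding the drug-receptor complex
#' @param doses data.frame with `time` (hours) and `amount` columns (further
#'   columns ignored), e.g. from [build_schedule()]
#' @param grid increasing time points (hours) at which to report
#' @return matrix with a `time` column and one column per compartment;
#'   attribute `"spec"` carries the model spec
#' @export
integrate_pk <- function(spec, doses, grid) {
  comps <- spec$compartments
  n <- length(comps)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  vols <- rep(1, n); names(vols) <- comps
  if (!is.null(spec$volumes)) vols[names(spec$volumes)] <- spec$volumes
  A <- matrix(0, n, n, dimnames = list(comps, comps))
  if (!is.null(spec$transfer) && nrow(spec$transfer)) {
    for (r in seq_len(nrow(spec$transfer))) {
      tr <- spec$transfer[r, ]
      if (tr$rate < 0) stop("transfer rates must be nonnegative")
      A[tr$to, tr$from] <- A[tr$to, tr$from] + tr$rate
      A[tr$from, tr$from] <- A[tr$from, tr$from] - tr$rate
    }
  }
  if (!is.null(spec$elim)) {
    if (any(spec$elim < 0)) stop("elimination rates must be nonnegative")
    for (nm in names(spec$elim)) A[nm, nm] <- A[nm, nm] - spec$elim[[nm]]
  }
  bind <- spec$binding
  deriv <- function(t, x, p) {
    dx <- as.vector(A %*% x)
    if (!is.null(bind)) {
      conc <- x[bind$compartment] / vols[bind$compartment]
      b <- x[bind$complex]
      db <- bind$kon * conc * (bind$r_tot - b) - bind$koff * b
      dx[match(bind$compartment, comps)] <- dx[match(bind$compartment, comps)] - db
      dx[match(bind$complex, comps)] <- dx[match(bind$complex, comps)] + db
    }
    list(dx)
  }
  x0 <- stats::setNames(rep(0, n), comps)
  doses <- doses[doses$amount > 0, , drop = FALSE]
  times <- sort(unique(c(grid, doses$time[doses$time <= max(grid)])))
  if (min(times) > 0) times <- c(0, times)
  # boluses at or before the first reported time enter the initial state, so
  # the trajectory at t = 0 reflects an administered t = 0 dose
  at_start <- doses$time <= times[1]
  if (any(at_start)) x0[spec$dosing] <- x0[spec$dosing] + sum(doses$amount[at_start])
  doses <- doses[!at_start, , drop = FALSE]
  evt <- NULL
  if (nrow(doses)) {
    evt <- list(data = data.frame(var = spec$dosing, time = doses$time,
                                  value = doses$amount, method = "add"))
  }
  sol <- deSolve::lsoda(x0, times, deriv, parms = NULL, events = evt,
                        rtol = 1e-8, atol = 1e-10)
  out <- sol[sol[, "time"] %in% grid, , drop = FALSE]
  out[out < 0 & out > -1e-9] <- 0  # integrator dust
  attr(out, "spec") <- spec
  out
}

#' Default PD1-antibody PK model specification
#'
#' A linear six-compartment placeholder for an IgG4 checkpoint antibody:
#' central, peripheral, tumour vasculature, endosomal and intestinal
#' compartments plus the drug-PD1 complex formed in the tumour compartment.
#' All rate constants are documented placeholders of physiologically
#' plausible magnitude (slow IgG elimination, fast high-affinity PD1
#' binding); substitute published values via the `pd1$model` config entry.
#'
#' @return a PK spec for [integrate_pk()]; amounts in mg, volumes in litres
#' @export
default_pd1_model <- function() {
  list(
    compartments = c("central", "peripheral", "tumour", "endosomal",
                     "intestinal", "complex"),
    transfer = data.frame(
      from = c("central", "peripheral", "central", "tumour", "central",
               "endosomal", "central"),
      to   = c("peripheral", "central", "tumour", "central", "endosomal",
               "central", "intestinal"),
      rate = c(0.05, 0.05, 0.02, 0.02, 0.02, 0.015, 0.005),
      stringsAsFactors = FALSE
    ),
    elim = c(central = 0.001, endosomal = 0.01, intestinal = 0.05),
    dosing = "central",
    volumes = c(central = 3, peripheral = 3, tumour = 0.1, endosomal = 0.5,
                intestinal = 1),
    binding = list(compartment = "tumour", complex = "complex",
                   kon = 10, koff = 0.01, r_tot = 1e-3)
  )
}

#' Receptor occupancy from a PK state
#'
#' Fraction of PD1 receptors bound by antibody; this fraction multiplies down
#' the effector-exhaustion propensity (`1 - occupancy`), so near-saturating
#' occupancy prevents exhaustion.
#'
#' @param complex bound-complex amount(s)
#' @param r_tot total receptor amount (> 0)
#' @return occupancy clamped to `[0, 1]`
#' @export
receptor_occupancy <- function(complex, r_tot) {
  if (r_tot <= 0) stop("total receptor must be positive")
  pmin(1, pmax(0, complex / r_tot))
}

#' K/PD chemotherapy kill rate with resistance
#'
#' `K(t) = epsilon * amount * exp(-lambda * t)`: the kill rate is
#' proportional to the amount of drug in the system and declines
#' exponentially with time since treatment start as resistance emerges.
#'
#' @param t hours since treatment start (>= 0)
#' @param amount drug amount in the system (e.g. mg, from the docetaxel PK)
#' @param params chemo parameter block: `epsilon` (per hour per amount unit),
#'   `lambda` (per hour)
#' @return kill rate per hour
#' @export
chemo_kill_rate <- function(t, amount, params = tme_config()$chemo) {
  if (any(t < 0)) stop("t must be nonnegative")
  params$epsilon * amount * exp(-params$lambda * t)
}

#' Chemotherapy death probability
#'
#' The per-application death probability is the kill rate divided by the
#' maximum kill rate. A kill rate exceeding `k_max` is clipped to probability
#' 1 with a warning.
#'
#' @param K kill rate (per hour), nonnegative
#' @param k_max maximum kill rate (per hour), positive
#' @return probability in `[0, 1]`
#' @export
chemo_death_probability <- function(K, k_max) {
  if (any(K < 0)) stop("kill rate must be nonnegative")
  if (k_max <= 0) stop("k_max must be positive")
  if (any(K > k_max)) {
    warning("kill rate exceeds k_max; clipping death probability to 1")
    K <- pmin(K, k_max)
  }
  K / k_max
}

#' Emax effect of the DNA-damage-response inhibitor
#'
#' `E = Emax * C / (EC50 + C)`; the effect acts as a death hazard on S-phase
#' cancer cells only.
#'
#' @param conc local drug concentration (>= 0)
#' @param params ddri parameter block: `emax`, `ec50`
#' @return effect in `[0, Emax)`
#' @export
ddr_effect <- function(conc, params = tme_config()$ddri) {
  if (any(conc < 0)) stop("concentration must be nonnegative")
  params$emax * conc / (params$ec50 + conc)
}

#' Oxygen-gradient scaling of the local drug concentration
#'
#' Drug reaches the lattice from the periphery like oxygen does, so the
#' systemic concentration is scaled by a nondecreasing function of the local
#' relative oxygen level: under the default linear mode the local level is
#' `systemic * oxygen`, giving lower exposure in the hypoxic core than at the
#' tumour edge.
#'
#' @param systemic systemic concentration
#' @param oxygen local relative oxygen in `[0, 1]`
#' @param mode `"oxygen_linear"` or `"none"`
#' @return local concentration
#' @export
local_concentration <- function(systemic, oxygen, mode = "oxygen_linear") {
  if (any(oxygen < 0 | oxygen > 1)) stop("oxygen must lie in [0, 1]")
  switch(mode,
         oxygen_linear = systemic * oxygen,
         none = systemic + 0 * oxygen,
         stop("unknown drug scaling mode: ", mode))
}

# one-compartment amount-in-system spec used for docetaxel and the DDRi
.one_compartment_spec <- function(k_elim, name = "central") {
  list(compartments = name,
       transfer = NULL,
       elim = stats::setNames(k_elim, name),
       dosing = name,
       volumes = stats::setNames(1, name))
}
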