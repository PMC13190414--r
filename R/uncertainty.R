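# Parameter uncertainty: the tabulated ranges, one-way (tornado) analysis,
# probabilistic sensitivity analysis and the CEAC.
#
# Survival-curve parameters carry no distribution in the input table and
# are excluded from the PSA (they can be explored through curve-level
# scenarios); the discount rate is OWSA-only, tested over 0-8%.

#' Parameter range table
#'
#' One row per uncertain parameter: base value, low/high range and the PSA
#' distribution family (`gamma` for costs, `beta` for utilities,
#' disutilities and probabilities, `none` for OWSA-only parameters).
#' Ranges are the published ones where stated; cost ranges are +/-20%.
#'
#' @param spec a `cea_spec`.
#' @return data.frame with columns `name`, `base`, `low`, `high`, `dist`.
#' @export
param_table <- function(spec) {
  p <- spec$prices; fu <- spec$followup; u <- spec$utilities; ae <- spec$ae
  pm20 <- function(x) c(0.8 * x, 1.2 * x)
  rows <- list()
  add <- function(name, base, low, high, dist)
    rows[[name]] <<- data.frame(name = name, base = base, low = low,
                                high = high, dist = dist)
  add("cost.sac_vial", p$sac_vial, 1052.68, 1579.02, "gamma")
  add("cost.pem_vial", p$pem_vial, 52.42, 78.62, "gamma")
  add("cost.carb_vial", p$carb_vial, 8.85, 13.27, "gamma")
  add("cost.cis_vial", p$cis_vial, 1.37, 2.05, "gamma")
  add("cost.osi_tab", p$osi_tab, 18.54, 27.81, "gamma")
  add("cost.bsc_cycle", p$bsc_cycle, 348.95, 523.43, "gamma")
  fu_ranges <- list(cbc = c(1.68, 2.52), biochem = c(20.16, 30.24),
                    urinalysis = c(2.02, 3.02), ct = c(8.96, 13.44),
                    mri = c(56.00, 84.00), nursing = c(2.91, 4.37),
                    bed = c(2.24, 3.36), consult = c(2.46, 3.70),
                    injection = c(0.65, 0.97), prep = c(3.81, 5.71))
  for (nm in names(fu_ranges))
    add(paste0("cost.fu.", nm), fu[[nm]], fu_ranges[[nm]][1],
        fu_ranges[[nm]][2], "gamma")
  ae_cost_ranges <- list(anemia = c(358.85, 538.27),
                         leukopenia = c(337.12, 505.68),
                         neutropenia = c(325.25, 487.87),
                         thrombocytopenia = c(2349.97, 3524.95))
  for (nm in names(ae_cost_ranges))
    add(paste0("cost.ae.", nm), unname(p$ae[nm]), ae_cost_ranges[[nm]][1],
        ae_cost_ranges[[nm]][2], "gamma")
  add("util.pfs", u$pfs, 0.536, 0.840, "beta")
  add("util.pd", u$pd, 0.031, 0.473, "beta")
  dis_ranges <- list(anemia = c(0.058, 0.088), leukopenia = c(0.160, 0.240),
                     neutropenia = c(0.160, 0.240),
                     thrombocytopenia = c(0.152, 0.228))
  for (nm in names(dis_ranges))
    add(paste0("disutil.", nm), ae$disutility[ae$name == nm],
        dis_ranges[[nm]][1], dis_ranges[[nm]][2], "beta")
  for (arm in c("sac_tmt", "chemo")) {
    col <- paste0("inc_", arm)
    for (i in seq_len(nrow(ae))) {
      b <- ae[[col]][i]; r <- pm20(b)
      add(paste0("inc.", arm, ".", ae$name[i]), b, r[1], r[2], "beta")
    }
  }
  add("discount", spec$discount_annual, 0, 0.08, "none")
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  bad <- tab$low > tab$base | tab$base > tab$high
  if (any(bad)) stop_config("param ranges must satisfy low <= base <= high")
  tab
}

#' Apply named parameter values to a spec
#'
#' Keys follow [param_table()] naming (`cost.*`, `util.*`, `disutil.*`,
#' `inc.<strategy>.*`, `discount`).  Unknown keys are a config error.
#'
#' @param spec a `cea_spec`.
#' @param values named numeric vector or list.
#' @return the modified, re-validated `cea_spec`.
#' @export
apply_params <- function(spec, values) {
  values <- unlist(values)
  for (key in names(values)) {
    val <- unname(values[key])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ok <- TRUE
    if (key == "discount") spec$discount_annual <- val
    else if (parts[1] == "cost" && length(parts) == 2 &&
             parts[2] %in% names(spec$prices)) spec$prices[[parts[2]]] <- val
    else if (parts[1] == "cost" && length(parts) == 3 && parts[2] == "fu" &&
             parts[3] %in% names(spec$followup)) spec$followup[[parts[3]]] <- val
    else if (parts[1] == "cost" && length(parts) == 3 && parts[2] == "ae" &&
             parts[3] %in% spec$ae$name) spec$prices$ae[parts[3]] <- val
    else if (parts[1] == "util" && parts[2] %in% names(spec$utilities))
      spec$utilities[[parts[2]]] <- val
    else if (parts[1] == "disutil" && parts[2] %in% spec$ae$name)
      spec$ae$disutility[spec$ae$name == parts[2]] <- val
    else if (parts[1] == "inc" && length(parts) == 3 &&
             parts[2] %in% names(spec$strategies) &&
             parts[3] %in% spec$ae$name) {
      col <- paste0("inc_", parts[2])
      spec$ae[[col]][spec$ae$name == parts[3]] <- val
    } else ok <- FALSE
    if (!ok) stop_config("unknown parameter key '%s'", key)
  }
  validate_spec(spec)
  spec
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-evaluates the deterministic model with each parameter at its low and
#' high value, all others at base, and reports the ICER at both ends.
#' Entries whose variation produces a non-positive incremental effect are
#' flagged, not dropped.
#'
#' @param spec a `cea_spec`.
#' @param engine `"psm"` or `"markov"`.
#' @param ranges optional subset of [param_table()] rows.
#' @param strategy,comparator strategies compared (defaults: the
#'   non-comparator strategy vs the spec comparator).
#' @return data.frame sorted by `spread` (descending) with columns `name`,
#'   `base`, `low`, `high`, `icer_low`, `icer_high`, `spread`, `flagged`.
#' @export
owsa <- function(spec, engine = "psm", ranges = param_table(spec),
                 strategy = NULL, comparator = spec$comparator) {
  engine <- match.arg(engine, c("psm", "markov"))
  strategy <- strategy %||% setdiff(names(spec$strategies), comparator)[1]
  icer_of <- function(s) {
    r <- run_cea(s, engine)$results
    r$icer[r$strategy == strategy]
  }
  n <- nrow(ranges)
  icer_low <- icer_high <- numeric(n); flagged <- logical(n)
  for (i in seq_len(n)) {
    vlow <- stats::setNames(ranges$low[i], ranges$name[i])
    vhigh <- stats::setNames(ranges$high[i], ranges$name[i])
    il <- icer_of(apply_params(spec, vlow))
    ih <- icer_of(apply_params(spec, vhigh))
    flagged[i] <- is.na(il) || is.na(ih)
    icer_low[i] <- il; icer_high[i] <- ih
  }
  out <- data.frame(name = ranges$name, base = ranges$base,
                    low = ranges$low, high = ranges$high,
                    icer_low = icer_low, icer_high = icer_high,
                    spread = abs(icer_high - icer_low), flagged = flagged)
  out[order(-out$spread), , drop = FALSE]
}

# method-of-moments PSA draws; sd = (high - low)/3.92 (ranges read as 95%
# intervals).  Disutilities are drawn as beta on the magnitude.  Infeasible
# beta moments fall back to uniform(low, high) with a warning.
draw_param <- function(n, base, low, high, dist) {
  sd <- (high - low) / 3.92
  if (sd == 0 || dist == "none") return(rep(base, n))
  if (dist == "gamma") {
    shape <- (base / sd)^2
    rate <- base / sd^2
    return(stats::rgamma(n, shape = shape, rate = rate))
  }
  if (dist == "beta") {
    v <- base * (1 - base) / sd^2 - 1
    if (base <= 0 || base >= 1 || v <= 0) {
      warning(sprintf(
        "beta moments infeasible (mean %.3g, sd %.3g); uniform fallback",
        base, sd))
      return(stats::runif(n, low, high))
    }
    return(stats::rbeta(n, base * v, (1 - base) * v))
  }
  stop_config("unknown PSA distribution '%s'", dist)
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: cost parameters are drawn from Gamma and
#' utility/disutility/probability parameters from Beta distributions, with
#' moments matched to (mean = base, sd = (high - low)/3.92).  Draws are made
#' parameter-by-parameter in [param_table()] row order from a single seeded
#' generator, so a run is bit-reproducible from (spec, n, seed).
#' Survival-curve parameters are held at base.
#'
#' @param spec a `cea_spec`.
#' @param n number of iterations (default `spec$psa$n`).
#' @param seed RNG seed (default `spec$psa$seed`).
#' @param engine engines to evaluate (`"both"`, `"psm"`, `"markov"`).
#' @param strategy,comparator strategies compared.
#' @return object of class `psa_result`: data.frame `samples` with one row
#'   per iteration (drawn parameters, then `dcost_<engine>`,
#'   `dqaly_<engine>`), plus attributes.
#' @export
run_psa <- function(spec, n = NULL, seed = NULL, engine = "both",
                    strategy = NULL, comparator = spec$comparator) {
  n <- n %||% spec$psa$n
  seed <- seed %||% spec$psa$seed
  engine <- match.arg(engine, c("both", "psm", "markov"))
  engines <- if (engine == "both") c("psm", "markov") else engine
  strategy <- strategy %||% setdiff(names(spec$strategies), comparator)[1]
  tab <- param_table(spec)
  tab <- tab[tab$dist != "none", , drop = FALSE]
  set.seed(seed)
  draws <- sapply(seq_len(nrow(tab)), function(i)
    draw_param(n, tab$base[i], tab$low[i], tab$high[i], tab$dist[i]))
  colnames(draws) <- tab$name
  out <- matrix(NA_real_, n, 2 * length(engines))
  colnames(out) <- as.vector(outer(c("dcost_", "dqaly_"), engines, paste0))
  for (it in seq_len(n)) {
    s_it <- apply_params(spec, draws[it, ])
    for (eng in engines) {
      r <- run_cea(s_it, eng)$results
      row <- r[r$strategy == strategy, ]
      out[it, paste0("dcost_", eng)] <- row$delta_cost
      out[it, paste0("dqaly_", eng)] <- row$delta_qalys
    }
  }
  samples <- cbind(data.frame(iteration = seq_len(n)), as.data.frame(draws),
                   as.data.frame(out))
  structure(samples, class = c("psa_result", "data.frame"),
            engines = engines, seed = seed, strategy = strategy,
            comparator = comparator)
}

#' Probability of cost-effectiveness at given thresholds
#'
#' Fraction of PSA iterations with positive incremental net monetary
#' benefit, \eqn{\lambda \Delta E - \Delta C > 0}.
#'
#' @param psa a `psa_result`.
#' @param wtp vector of willingness-to-pay thresholds (USD/QALY).
#' @param engine which engine's increments to use.
#' @return data.frame with columns `wtp`, `prob_ce`.
#' @export
ceac <- function(psa, wtp, engine = attr(psa, "engines")[1]) {
  if (!length(wtp)) stop_config("empty WTP grid")
  dc <- psa[[paste0("dcost_", engine)]]
  de <- psa[[paste0("dqaly_", engine)]]
  if (is.null(dc)) stop_config("engine '%s' not present in PSA", engine)
  data.frame(wtp = wtp,
             prob_ce = vapply(wtp, function(l) mean(l * de - dc > 0),
                              numeric(1)))
}
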