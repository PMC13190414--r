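# Top-level runner and result object.

#' Run the cost-effectiveness analysis
#'
#' Runs the requested engine(s) for every strategy in the spec, totals the
#' discounted accruals and forms incremental comparisons against the
#' comparator strategy.
#'
#' @param spec a `cea_spec`, e.g. [base_case_spec()].
#' @param engine `"psm"`, `"markov"` or `"both"`; defaults to the spec's.
#' @return object of class `cea_result` with elements
#'   \describe{
#'     \item{results}{data.frame: engine, strategy, total_cost, total_qalys,
#'       total_lys, delta_cost, delta_qalys, icer, dominance}
#'     \item{traces}{nested list of `cohort_trace` by engine and strategy}
#'     \item{log}{character vector of engine warnings (curve capping,
#'       transition clamping)}
#'     \item{spec}{the input spec}
#'   }
#' @examples
#' \donttest{
#' res <- run_cea(base_case_spec())
#' print(res)
#' }
#' @export
run_cea <- function(spec, engine = NULL) {
  stopifnot(inherits(spec, "cea_spec"))
  engine <- match.arg(engine %||% spec$engine, c("both", "psm", "markov"))
  engines <- if (engine == "both") c("psm", "markov") else engine
  rows <- list(); traces <- list(); logs <- character()
  for (eng in engines) {
    traces[[eng]] <- list()
    totals <- list()
    for (nm in names(spec$strategies)) {
      tr <- if (eng == "psm") run_psm(spec, nm) else run_markov(spec, nm)
      traces[[eng]][[nm]] <- tr
      logs <- c(logs, attr(tr, "log"))
      totals[[nm]] <- trace_totals(tr)
    }
    base <- totals[[spec$comparator]]
    for (nm in names(spec$strategies)) {
      cmp <- if (nm == spec$comparator)
        list(delta_cost = NA_real_, delta_qalys = NA_real_,
             icer = NA_real_, dominance = NA_character_)
      else icer(totals[[nm]], base)
      rows[[paste(eng, nm)]] <- data.frame(
        engine = eng, strategy = nm,
        label = spec$strategies[[nm]]$label %||% nm,
        total_cost = totals[[nm]]$total_cost,
        total_qalys = totals[[nm]]$total_qalys,
        total_lys = totals[[nm]]$total_lys,
        delta_cost = cmp$delta_cost, delta_qalys = cmp$delta_qalys,
        icer = cmp$icer, dominance = cmp$dominance)
    }
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 traces = traces, log = logs, spec = spec),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness results (discounted)\n")
  r <- x$results
  fm <- function(v, d = 2) ifelse(is.na(v), "-", formatC(v, format = "f",
                                                         digits = d, big.mark = ","))
  out <- data.frame(Model = toupper(r$engine), Treatment = r$label,
                    `Total cost` = fm(r$total_cost),
                    `D Cost` = fm(r$delta_cost),
                    QALYs = fm(r$total_qalys),
                    `D QALYs` = fm(r$delta_qalys),
                    `ICER ($/QALY)` = fm(r$icer), check.names = FALSE)
  print(out, row.names = FALSE)
  if (length(x$log)) cat("log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  r <- object$results
  cmp <- r[!is.na(r$icer) | !is.na(r$dominance), ]
  cat(sprintf("WTP threshold: %s USD/QALY\n",
              format(object$spec$wtp, big.mark = ",")))
  print(object)
  for (i in seq_len(nrow(cmp))) {
    verdict <- if (!is.na(cmp$icer[i]) && cmp$icer[i] <= object$spec$wtp)
      "cost-effective" else "not cost-effective"
    cat(sprintf("%s / %s vs comparator: %s at the stated threshold\n",
                toupper(cmp$engine[i]), cmp$label[i], verdict))
  }
  invisible(object)
}

#' Render results in the seven-column report layout
#'
#' @param result a `cea_result`.
#' @param json_path optional path; when given, the full-precision results
#'   are also written as JSON.
#' @return data.frame with columns Model, Treatment, Total cost, Delta Cost,
#'   QALYs, Delta QALYs, ICER (comparator rows show empty deltas).  Values
#'   are rounded to 2 decimals in the table only.
#' @export
render_results <- function(result, json_path = NULL) {
  r <- result$results
  fm <- function(v) ifelse(is.na(v), "", formatC(v, format = "f", digits = 2,
                                                 big.mark = ","))
  tab <- data.frame(Model = toupper(r$engine), Treatment = r$label,
                    `Total cost` = fm(r$total_cost),
                    `Delta Cost` = fm(r$delta_cost),
                    QALYs = fm(r$total_qalys),
                    `Delta QALYs` = fm(r$delta_qalys),
                    `ICER ($/QALY)` = fm(r$icer),
                    check.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(r, json_path, dataframe = "rows", digits = NA,
                         na = "null")
  tab
}

#' Write a cohort trace as CSV
#'
#' @param trace a `cohort_trace`.
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
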