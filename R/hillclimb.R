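# Randomised hill climbing over (ID_T, Q_T, QR_T) to minimise BUSCO cost.

#' Hill-climbing configuration
#'
#' @param iterations Number of random-walk iterations (the default
#'   candidate at iteration 0 is evaluated in addition).
#' @param step_increment Fixed step scale; each iteration adds
#'   `step_increment * U(0,1)` (independent draws) to each threshold.
#' @param plateau_limit Number of consecutive iterations with unchanged
#'   cost that triggers a restart from fresh random thresholds.
#' @param best_x Number of unique best assemblies retained.
#' @param weights A [busco_weights()] vector.
#' @param seed Integer seed for the run's random number stream.
#' @param start Optional fixed [purge_thresholds()] starting point; when
#'   absent the walk starts from random thresholds.
#' @return A `hillclimb_config` list.
#' @export
hillclimb_config <- function(iterations = 50000, step_increment = 1e-4,
                             plateau_limit = 50, best_x = 10,
                             weights = busco_weights(), seed = 1L,
                             start = NULL) {
  stopifnot(iterations >= 1, step_increment > 0, plateau_limit >= 1,
            best_x >= 1)
  if (!is.null(start) && !inherits(start, "purge_thresholds")) {
    stop("start must be a purge_thresholds object or NULL", call. = FALSE)
  }
  structure(list(iterations = as.integer(iterations),
                 step_increment = step_increment,
                 plateau_limit = as.integer(plateau_limit),
                 best_x = as.integer(best_x),
                 weights = weights,
                 seed = as.integer(seed),
                 start = start),
            class = "hillclimb_config")
}

#' Minimise BUSCO cost by randomised hill climbing
#'
#' Starting from the default thresholds (0.70, 0.70, 0.70) at iteration 0
#' — so the optimised result can never be worse than the default single
#' purge — and then from a random (or user-fixed) point, each iteration
#' evaluates the candidate assembly at the current thresholds, pushes it
#' into the bounded unique-candidate store, and takes a randomised step in
#' the positive direction: `step_increment * U(0,1)` added independently to
#' each of ID_T, Q_T and QR_T. When the cost has not changed for
#' `plateau_limit` consecutive iterations, or any threshold walks past its
#' upper limit of 1.00, the walk restarts from fresh thresholds drawn
#' uniformly from (0, 1] (QR_T is capped at 1 like ID_T and Q_T: the
#' symmetric QR window already covers ratios above 1). The cost is
#' evaluated immediately at each restart point.
#'
#' @param table An `alignment_table`, already passed through
#'   [filter_eligible()].
#' @param catalog A `busco_catalog`.
#' @param all_contigs Character vector of all contig names in the assembly.
#' @param config A [hillclimb_config()].
#' @return A list with elements `store` (a `candidate_store` of the
#'   `best_x` unique lowest-cost candidates) and `trace` (a data frame with
#'   one row per evaluation: `iteration`, `id_t`, `q_t`, `qr_t`, `cost`,
#'   `best_cost`, `restart`).
#' @export
hill_climb <- function(table, catalog, all_contigs,
                       config = hillclimb_config()) {
  all_contigs <- as.character(all_contigs)
  used <- unique(c(table$query_name, table$target_name))
  missing <- setdiff(used, all_contigs)
  if (length(missing)) {
    stop("alignment table names contig(s) absent from all_contigs: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }

  runner <- make_climb_runner(table, catalog, all_contigs, config$weights)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(config$seed)

  n_eval <- config$iterations + 1L
  trace <- list(iteration = integer(n_eval), id_t = numeric(n_eval),
                q_t = numeric(n_eval), qr_t = numeric(n_eval),
                cost = numeric(n_eval), best_cost = numeric(n_eval),
                restart = logical(n_eval))
  store <- candidate_store(config$best_x)
  best <- Inf

  record <- function(k, thr, cost, restart) {
    trace$iteration[k] <<- k - 1L
    trace$id_t[k] <<- thr[1]; trace$q_t[k] <<- thr[2]
    trace$qr_t[k] <<- thr[3]
    trace$cost[k] <<- cost
    best <<- min(best, cost)
    trace$best_cost[k] <<- best
    trace$restart[k] <<- restart
  }

  # iteration 0: the default -HC thresholds, always evaluated
  thr <- c(0.70, 0.70, 0.70)
  res <- runner(thr)
  store <- store_push(store, res$candidate)
  record(1L, thr, res$cost, FALSE)

  fresh <- function() stats::runif(3)
  thr <- if (is.null(config$start)) {
    fresh()
  } else {
    c(config$start$id, config$start$q, config$start$qr)
  }
  restart_flag <- TRUE  # iterations after a (re)start point
  plateau <- 0L
  prev_cost <- NA_real_

  for (k in seq_len(config$iterations) + 1L) {
    res <- runner(thr)
    store <- store_push(store, res$candidate)
    record(k, thr, res$cost, restart_flag)
    restart_flag <- FALSE

    if (!is.na(prev_cost) &&
        (res$cost == prev_cost || (is.infinite(res$cost) &&
                                     is.infinite(prev_cost)))) {
      plateau <- plateau + 1L
    } else {
      plateau <- 0L
    }
    prev_cost <- res$cost

    thr <- thr + config$step_increment * stats::runif(3)
    if (plateau >= config$plateau_limit || any(thr > 1)) {
      thr <- fresh()
      restart_flag <- TRUE
      plateau <- 0L
      prev_cost <- NA_real_
    }
  }

  list(store = store,
       trace = as.data.frame(trace, stringsAsFactors = FALSE))
}

# Precomputes vectorised structures so that one evaluation is a handful of
# vector operations; returns a closure mapping c(id, q, qr) to the scored
# candidate.
make_climb_runner <- function(table, catalog, all_contigs, weights) {
  id_v <- table$ID; q_v <- table$Q; qr_v <- table$QR
  q_idx <- match(table$query_name, all_contigs)
  inc <- busco_incidence(catalog, all_contigs)
  n <- length(all_contigs)
  w_m <- weights[["m"]]; w_d <- weights[["d"]]
  w_f <- weights[["f"]]; w_s <- weights[["s"]]
  function(thr) {
    qrp <- exp(-log2(thr[3]))
    lo <- min(thr[3], qrp); hi <- max(thr[3], qrp)
    pass <- id_v >= thr[1] & q_v >= thr[2] & qr_v >= lo & qr_v <= hi
    ret <- rep(1, n)
    purged_idx <- unique(q_idx[pass])
    ret[purged_idx] <- 0
    cnt <- counts_from_incidence(inc, ret)
    cost <- if (cnt[["S"]] == 0) {
      Inf
    } else {
      (w_m * cnt[["M"]] + w_d * cnt[["D"]] + w_f * cnt[["F"]]) /
        (w_s * cnt[["S"]])
    }
    cand <- structure(list(retained = all_contigs[ret == 1],
                           purged = all_contigs[purged_idx],
                           counts = structure(cnt, class = "busco_counts"),
                           cost = cost,
                           thresholds = structure(
                             list(id = thr[1], q = thr[2], qr = thr[3],
                                  qr_prime = qrp),
                             class = "purge_thresholds")),
                      class = "candidate_assembly")
    list(candidate = cand, cost = cost)
  }
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Normalise a cost trace to \[0, 1\]
#'
#' Subtracts the minimum observed cost and divides by the observed range,
#' the usual rescaling for comparing cost trajectories across runs or
#' datasets. A constant (or single-element) trace yields all zeros with a
#' warning.
#'
#' @param costs A numeric vector of costs, or a trace data frame from
#'   [hill_climb()] (its `cost` column is used). Infinite entries are kept
#'   out of the min/max and map to 1.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_costs <- function(costs) {
  if (is.data.frame(costs)) {
    costs <- costs$cost
  }
  if (length(costs) == 0L) {
    stop("empty cost trace", call. = FALSE)
  }
  finite <- is.finite(costs)
  if (!any(finite)) {
    warning("no finite costs in trace; returning zeros", call. = FALSE)
    return(rep(0, length(costs)))
  }
  lo <- min(costs[finite]); hi <- max(costs[finite])
  if (hi == lo) {
    warning("degenerate cost trace (max == min); returning zeros",
            call. = FALSE)
    out <- rep(0, length(costs))
    out[!finite] <- 1
    if (all(finite)) out[] <- 0
    return(out)
  }
  out <- (costs - lo) / (hi - lo)
  out[!finite] <- 1
  out
}

#' Write a hill-climbing trace as TSV
#'
#' @param trace The trace data frame from [hill_climb()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
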