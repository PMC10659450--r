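#' Simulated-annealing search configuration
#'
#' The annealing search walks the component graph looking for MDSs with
#' extremal remaining path length: a bounded number of random F-moves
#' samples each visited component (the within-component range is
#' empirically O(k), so a small sample suffices), then one I-move jumps to
#' a neighboring component, accepted when it improves the local extremum
#' and otherwise with Metropolis probability \eqn{e^{-|\Delta|/T}} under a
#' geometric cooling schedule.
#'
#' @param objective `"minimize"` or `"maximize"` the remaining path
#'   length.
#' @param fmoves_per_component random F-moves evaluated per visited
#'   component; default `2 * k`.
#' @param iterations number of component-level iterations.
#' @param t0 initial temperature; default `k` (RPL deltas are O(k) within
#'   a component, so this accepts most early jumps).
#' @param cooling geometric cooling factor per iteration, in (0, 1).
#' @param seed integer; every source of randomness in [anneal()] derives
#'   from it, so (config, seed) reproduces a run exactly.
#' @return a list of class `anneal_config`.
#' @export
anneal_config <- function(objective = c("minimize", "maximize"),
                          fmoves_per_component = NULL,
                          iterations = 100L,
                          t0 = NULL,
                          cooling = 0.95,
                          seed = 1L) {
  objective <- match.arg(objective)
  if (cooling <= 0 || cooling >= 1) err_input("cooling must be in (0, 1)")
  structure(list(objective = objective,
                 fmoves_per_component = fmoves_per_component,
                 iterations = as.integer(iterations),
                 t0 = t0, cooling = cooling, seed = as.integer(seed)),
            class = "anneal_config")
}

#' Search for extremal remaining path lengths
#'
#' Each iteration (1) performs `fmoves_per_component` random F-moves
#' inside the current component, evaluating the remaining path length of
#' every set visited and keeping the local extremum, (2) computes the
#' component's I-move list from the current MDS ([component_i_moves()]),
#' (3) if the list is empty restarts from a seeded [random_mds_walk()]
#' perturbation (I-moves allowed), otherwise picks one I-move uniformly,
#' realizes it from a host MDS of the current component and jumps, and
#' (4) accepts the new component when its local extremum improves on the
#' current one, else with probability \eqn{e^{-|\Delta|/T}}, then cools
#' `T` geometrically. The best set ever evaluated is returned; all
#' evaluated sets are MDSs because moves preserve MDS-ness.
#'
#' @param space a [kmer_space()].
#' @param config an [anneal_config()].
#' @param seed_mds starting MDS; defaults to [mykkeltveit_set()].
#' @return list of class `anneal_result`: `best_set`, `best_value`
#'   (calibrated remaining path length of `best_set`), `trace` (data frame
#'   of iteration, a digest of the current MDS, and the best value so far
#'   — monotone), and `l_report` with the smallest and largest RPL seen
#'   anywhere during the run.
#' @examples
#' res <- anneal(kmer_space(2, 4), anneal_config(iterations = 20))
#' res$best_value
#' @export
anneal <- function(space, config = anneal_config(), seed_mds = NULL) {
  if (!inherits(config, "anneal_config")) err_input("expected anneal_config")
  if (is.null(seed_mds)) seed_mds <- mykkeltveit_set(space)
  check_kmer_set(seed_mds)
  if (!is_pcr_set(seed_mds) || !is_decycling(seed_mds))
    err_input("seed_mds is not an MDS")
  k <- space$k
  n_f <- if (is.null(config$fmoves_per_component)) 2L * k
         else as.integer(config$fmoves_per_component)
  temp <- if (is.null(config$t0)) k else config$t0
  if (temp <= 0) err_input("t0 must be positive")
  sign <- if (config$objective == "minimize") 1 else -1
  rpl <- function(M) remaining_path_length(M)

  with_seed(config$seed, {
    current <- seed_mds
    cur_val <- rpl(current)
    best_set <- current
    best_val <- cur_val
    low <- cur_val
    high <- cur_val
    note <- function(M, v) {
      if (v < low) low <<- v
      if (v > high) high <<- v
      if (sign * (v - best_val) < 0) {
        best_val <<- v
        best_set <<- M
      }
    }
    # random F-move walk inside the component of M, tracking the local
    # extremum of the remaining path length over the sets visited
    sample_component <- function(M) {
      ext <- rpl(M)
      note(M, ext)
      for (s in seq_len(n_f)) {
        fs <- valid_f_moves(M)
        M <- apply_f_move(M, fs[sample.int(length(fs), 1L)])
        v <- rpl(M)
        note(M, v)
        if (sign * (v - ext) < 0) ext <- v
      }
      list(M = M, ext = ext)
    }
    cur <- sample_component(current)
    trace <- vector("list", config$iterations)
    for (it in seq_len(config$iterations)) {
      im <- component_i_moves(cur$M)
      if (nrow(im) == 0L) {
        # no way out by I-move: restart from a perturbed MDS
        cand <- sample_component(random_mds_walk(cur$M, 4L * k,
                                                 allow_imoves = TRUE))
        cur <- cand
      } else {
        pick <- sample.int(nrow(im), 1L)
        comp <- enumerate_component(cur$M, want_members = TRUE,
                                    want_rpl = FALSE)
        host <- find_mds_with_pattern(comp, im$f[pick], im$mask[pick])
        cand <- sample_component(apply_i_move(host, im$f[pick],
                                              im$mask[pick]))
        delta <- sign * (cand$ext - cur$ext)
        if (delta < 0 || runif(1) < exp(-abs(delta) / temp)) cur <- cand
      }
      temp <- temp * config$cooling
      trace[[it]] <- data.frame(iteration = it,
                                digest = format(cur$M),
                                value = best_val)
    }
    structure(list(best_set = best_set,
                   best_value = best_val,
                   trace = do.call(rbind, trace),
                   l_report = c(l_min_estimate = low,
                                l_max_estimate = high)),
              class = "anneal_result")
  })
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("<anneal_result best_value=%d, rpl range seen [%d, %d]>\n",
              x$best_value, x$l_report[[1]], x$l_report[[2]]))
  invisible(x)
}
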