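#' Enumerate one component of the MDS graph
#'
#' The MDS graph has all MDSs as nodes and F-moves as edges; its
#' components are strongly connected, \eqn{\sigma^{k-1}}-partite (every
#' F-move edge advances the layer index by one, cyclically) and have girth
#' \eqn{\sigma^{k-1}}. Because components are strongly connected, the
#' forward F-move closure of any member is the whole component, which is
#' enumerated here layer by layer, keeping only the current and next layer
#' resident plus a ledger of visited canonical keys. The layer closure is
#' checked on every cross edge; a violation would falsify the component
#' structure and raises an error rather than continuing.
#'
#' @param M0 a [kmer_set()] that is an MDS (one k-mer per rotation orbit
#'   and decycling); checked.
#' @param want_members keep every member MDS (needed by
#'   [find_mds_with_pattern()]).
#' @param want_rpl compute the remaining-path-length range over members.
#' @return An object of class `mds_component`: `representative` (the
#'   lexicographically smallest member, also the canonical component key),
#'   `size`, `layer_sizes` (length \eqn{\sigma^{k-1}}, member counts per
#'   layer with the seed in layer 0), `imoves` (the component's full
#'   I-move list, a data frame sorted by `(f, mask)`), `rpl_min` /
#'   `rpl_max` (calibrated convention, `NA` if `want_rpl = FALSE`), and
#'   `members` (integer matrix, one MDS per row in traversal order, when
#'   requested).
#' @examples
#' sp <- kmer_space(2, 4)
#' comp <- enumerate_component(mykkeltveit_set(sp))
#' comp$size
#' @export
enumerate_component <- function(M0, want_members = TRUE, want_rpl = TRUE) {
  check_kmer_set(M0)
  if (!is_pcr_set(M0) || !is_decycling(M0))
    err_input("M0 is not an MDS")
  sp <- M0$space
  res <- cpp_enumerate_component(M0$members, sp$sigma, sp$k,
                                 want_members, want_rpl)
  delta <- if (want_rpl) rpl_calibration_offset() else 0L
  structure(list(
    space = sp,
    representative = kmer_set(res$representative, sp),
    size = res$size,
    layer_sizes = res$layer_sizes,
    imoves = as.data.frame(cpp_component_imoves(res$representative,
                                                sp$sigma, sp$k)),
    rpl_min = if (want_rpl) res$rpl_min - delta else NA_integer_,
    rpl_max = if (want_rpl) res$rpl_max - delta else NA_integer_,
    members = if (want_members) res$members else NULL
  ), class = "mds_component")
}

#' @export
print.mds_component <- function(x, ...) {
  cat(sprintf(paste0("<mds_component sigma=%d k=%d: %d MDSs, %d I-moves, ",
                     "rpl [%s, %s]>\n"),
              x$space$sigma, x$space$k, x$size, nrow(x$imoves),
              x$rpl_min, x$rpl_max))
  invisible(x)
}

#' Component-level I-move list from a single MDS
#'
#' Computes \eqn{\mathcal{I}(\chi)}, the set of I-moves valid in at least
#' one MDS of the component of `M`, from `M` alone: the cycles that hit
#' `M` exactly once (constrained cycles) are the same for every member of
#' the component, and an I-move `f|m` is invalid throughout the component
#' exactly when some constrained cycle uses an edge \eqn{af \to fb} with
#' \eqn{m_a = 1, m_b = 0} (the move would leave that cycle unhit). Edges
#' on constrained cycles are tagged with one forward and one backward
#' `M`-avoiding search per member of `M`, so the runtime is independent of
#' the component's size.
#'
#' @param M a [kmer_set()] that is an MDS; checked.
#' @return data frame with integer columns `f` and `mask`, sorted.
#' @examples
#' sp <- kmer_space(2, 5)
#' nrow(component_i_moves(mykkeltveit_set(sp)))  # 0
#' @export
component_i_moves <- function(M) {
  check_kmer_set(M)
  if (!is_pcr_set(M) || !is_decycling(M)) err_input("M is not an MDS")
  as.data.frame(cpp_component_imoves(M$members, M$space$sigma, M$space$k))
}

#' Find a member MDS in which an I-move is valid
#'
#' Every I-move in a component's list \eqn{\mathcal{I}(\chi)} is valid in
#' at least one member MDS; this scans the component's members in
#' traversal order and returns the first such host. Failure to find one
#' would falsify the constrained-cycle characterization and raises an
#' invariant error.
#'
#' @param component an [enumerate_component()] result with members kept.
#' @param f,mask the I-move.
#' @return the host [kmer_set()].
#' @export
find_mds_with_pattern <- function(component, f, mask) {
  if (!inherits(component, "mds_component") || is.null(component$members))
    err_input("need an mds_component enumerated with want_members = TRUE")
  sp <- component$space
  row <- cpp_find_host(component$members, sp$sigma, sp$k,
                       as.integer(f), as.integer(mask))
  if (row == 0L)
    err_invariant("no member MDS hosts I-move ", f, "|", mask,
                  ": constrained-cycle invariant falsified")
  kmer_set(component$members[row, ], sp)
}

#' Traverse the whole component graph
#'
#' Breadth-first traversal over components of the MDS graph: enumerate a
#' component, compute its I-move list, realize each I-move from a host
#' member, apply it to jump to a neighboring component, and recurse on
#' components not yet seen. Components are identified exactly by their
#' canonical representative (lexicographically smallest member MDS);
#' completeness of the traversal — that every MDS is reached — is
#' conditional on the connectivity of the component graph, which has been
#' verified exhaustively for the binary alphabet up to `k = 7` but is open
#' in general.
#'
#' @param space a [kmer_space()].
#' @param seed_mds starting MDS; defaults to [mykkeltveit_set()].
#' @param want_rpl compute per-component remaining-path-length ranges.
#' @return An object of class `mds_component_graph`: `components` (list of
#'   [enumerate_component()] results, discovery order), `edges` (two-column
#'   matrix of component ids, undirected I-move adjacency, deduplicated),
#'   and `n_mds_total`.
#' @examples
#' g <- enumerate_all_components(kmer_space(2, 4))
#' length(g$components)  # 3
#' g$n_mds_total         # 30
#' @export
enumerate_all_components <- function(space, seed_mds = NULL,
                                     want_rpl = TRUE) {
  if (is.null(seed_mds)) seed_mds <- mykkeltveit_set(space)
  check_kmer_set(seed_mds)
  comp_of <- new.env(parent = emptyenv())  # member key -> component id
  components <- list()
  pending_edges <- list()  # (source id, member codes of target)
  queue <- list(seed_mds$members)
  while (length(queue)) {
    m <- queue[[1L]]
    queue <- queue[-1L]
    if (!is.null(comp_of[[set_key_str(m)]])) next
    comp <- enumerate_component(kmer_set(m, space), want_members = TRUE,
                                want_rpl = want_rpl)
    id <- length(components) + 1L
    components[[id]] <- comp
    for (i in seq_len(nrow(comp$members)))
      comp_of[[set_key_str(comp$members[i, ])]] <- id
    im <- comp$imoves
    for (i in seq_len(nrow(im))) {
      host <- find_mds_with_pattern(comp, im$f[i], im$mask[i])
      dest <- apply_i_move(host, im$f[i], im$mask[i])
      pending_edges[[length(pending_edges) + 1L]] <- list(id, dest$members)
      queue[[length(queue) + 1L]] <- dest$members
    }
  }
  edges <- matrix(integer(0), ncol = 2)
  if (length(pending_edges)) {
    epairs <- t(vapply(pending_edges, function(pe) {
      to <- comp_of[[set_key_str(pe[[2L]])]]
      if (is.null(to))
        err_invariant("I-move destination escaped the traversal")
      sort(c(pe[[1L]], to))
    }, integer(2)))
    if (any(epairs[, 1] == epairs[, 2]))
      err_invariant("I-move stayed inside its component")
    edges <- unique(epairs)
  }
  structure(list(space = space,
                 components = components,
                 edges = edges,
                 n_mds_total = sum(vapply(components, `[[`, 0, "size"))),
            class = "mds_component_graph")
}

set_key_str <- function(codes) paste(codes, collapse = ",")

#' @export
print.mds_component_graph <- function(x, ...) {
  cat(sprintf("<mds_component_graph sigma=%d k=%d: %d components, %s MDSs, %d I-move edges>\n",
              x$space$sigma, x$space$k, length(x$components),
              format(x$n_mds_total, big.mark = " "), nrow(x$edges)))
  invisible(x)
}

#' Remaining-path-length range of a component
#'
#' @param component an [enumerate_component()] result with `want_rpl`.
#' @return integer vector `c(min, max)` over all member MDSs, in the
#'   calibrated convention.
#' @export
component_rpl_range <- function(component) {
  if (!inherits(component, "mds_component")) err_input("expected a component")
  if (is.na(component$rpl_min))
    err_input("component was enumerated without RPL computation")
  c(component$rpl_min, component$rpl_max)
}
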