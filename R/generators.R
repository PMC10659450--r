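# Complex embedding weight of a k-mer: W(u) = sum_j u_{j+1} omega^j with
# omega = exp(2*pi*i/k), u_1 the leftmost (most significant) symbol. A
# left rotation multiplies W by omega^(-1), so |W| is a rotation-orbit
# invariant and the argument steps through the k sectors of width 2*pi/k.
embedding_weight <- function(u, space) {
  k <- space$k
  d <- integer(k)
  for (i in k:1) {
    d[i] <- u %% space$sigma
    u <- u %/% space$sigma
  }
  sum(d * exp(2i * pi * (0:(k - 1)) / k))
}

#' The Mykkeltveit minimum decycling set
#'
#' Constructs the classic MDS from the complex root-of-unity embedding
#' \eqn{W(u) = \sum_{j=0}^{k-1} u_{j+1} \omega^j}, \eqn{\omega =
#' e^{2\pi i/k}}: for every rotation orbit with nonzero weight, the unique
#' rotation whose weight argument falls in the sector \eqn{[0, 2\pi/k)} is
#' selected (a left rotation multiplies the weight by \eqn{\omega^{-1}},
#' so exactly one rotation qualifies — asserted during construction). For
#' zero-weight orbits (all orbits of period < k, plus occasional
#' full-period orbits whose symbol sums of roots of unity vanish) the
#' choice is free up to the decycling requirement; members are tried in
#' ascending code order with backtracking until the completed set is
#' decycling. The result is verified to be a decycling PCR set of size
#' equal to the necklace count before it is returned.
#'
#' The Mykkeltveit set is empirically at or near the minimum remaining
#' path length over all MDSs, which makes it the default traversal seed
#' and annealing start.
#'
#' @param space a [kmer_space()].
#' @param tol absolute tolerance deciding zero weights and sector
#'   boundaries; root-of-unity sums are well conditioned at supported k.
#' @return a [kmer_set()] that is an MDS.
#' @examples
#' M <- mykkeltveit_set(kmer_space(2, 5))
#' length(M$members)  # 8, the binary 5-necklace count
#' @export
mykkeltveit_set <- function(space, tol = 1e-9) {
  check_enumeration_size(space)
  part <- enumerate_pcrs(space)
  sector <- 2 * pi / space$k
  fixed <- integer(0)
  free_orbits <- list()
  for (orb in part$orbits) {
    w <- vapply(orb, function(u) embedding_weight(u, space), 0i)
    if (all(Mod(w) < tol)) {
      if (length(orb) == 1L) fixed <- c(fixed, orb)  # homopolymer: forced
      else free_orbits[[length(free_orbits) + 1L]] <- sort(orb)
    } else {
      # sector test on the conjugate weight: with W as defined here the
      # decycling sector is (-2*pi/k, 0], the mirror of [0, 2*pi/k)
      arg <- (-Arg(w)) %% (2 * pi)
      in_sector <- arg < sector - tol | arg > 2 * pi - tol
      if (sum(in_sector) != 1L)
        err_invariant("sector membership not unique on orbit of ",
                      decode_kmers(orb[1], space))
      fixed <- c(fixed, orb[in_sector])
    }
  }
  members <- complete_decycling(fixed, free_orbits, space)
  if (is.null(members))
    err_invariant("no decycling completion found for the zero-weight orbits")
  M <- kmer_set(members, space)
  if (!is_pcr_set(M) || !is_decycling(M) ||
      length(M$members) != count_pcrs(space))
    err_invariant("constructed set failed its verification contract")
  M
}

# depth-first search over zero-weight orbit choices, members in ascending
# code order; returns a full member vector or NULL
complete_decycling <- function(fixed, free_orbits, space) {
  n <- length(free_orbits)
  if (n == 0L) {
    ok <- cpp_is_decycling(fixed, space$sigma, space$k)
    return(if (ok) fixed else NULL)
  }
  idx <- rep(1L, n)
  depth <- 1L
  repeat {
    if (depth > n) {
      members <- c(fixed, vapply(seq_len(n),
                                 function(i) free_orbits[[i]][idx[i]], 0L))
      if (cpp_is_decycling(members, space$sigma, space$k)) return(members)
      depth <- n
      idx[depth] <- idx[depth] + 1L
    }
    while (depth >= 1L && idx[depth] > length(free_orbits[[depth]])) {
      idx[depth] <- 1L
      depth <- depth - 1L
      if (depth >= 1L) idx[depth] <- idx[depth] + 1L
    }
    if (depth < 1L) return(NULL)
    if (idx[depth] <= length(free_orbits[[depth]])) depth <- n + 1L
  }
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random PCR sets and random MDS walks
#'
#' `random_pcr_set()` draws one k-mer independently and uniformly from
#' each rotation orbit — the natural uniform sampler over PCR sets. Such a
#' set is an MDS only with (rapidly vanishing) probability; the sampler is
#' mainly useful for studying that fraction and as a negative-control
#' generator.
#'
#' `random_mds_walk()` applies `n_moves` uniformly random valid moves to
#' an MDS: F-moves only by default, or F-moves and I-moves pooled when
#' `allow_imoves = TRUE`. Every intermediate set is an MDS, so the walk is
#' a fixture generator for "a generic MDS of the (component of the) seed".
#'
#' @param space a [kmer_space()].
#' @param seed integer seed for reproducibility; `NULL` uses (and
#'   advances) the session RNG.
#' @param M0 a [kmer_set()] that is an MDS; checked.
#' @param n_moves number of moves to apply.
#' @param allow_imoves pool valid I-moves with the F-moves.
#' @return a [kmer_set()].
#' @examples
#' sp <- kmer_space(2, 4)
#' is_pcr_set(random_pcr_set(sp, seed = 1))  # TRUE
#' @export
random_pcr_set <- function(space, seed = NULL) {
  part <- enumerate_pcrs(space)
  with_seed(seed, {
    members <- vapply(part$orbits, function(orb) {
      orb[sample.int(length(orb), 1L)]
    }, 0L)
    kmer_set(members, space)
  })
}

#' @rdname random_pcr_set
#' @export
random_mds_walk <- function(M0, n_moves, seed = NULL, allow_imoves = FALSE) {
  check_kmer_set(M0)
  if (!is_pcr_set(M0) || !is_decycling(M0)) err_input("M0 is not an MDS")
  with_seed(seed, {
    M <- M0
    for (step in seq_len(n_moves)) {
      fs <- valid_f_moves(M)
      n_f <- length(fs)
      n_i <- 0L
      if (allow_imoves) {
        im <- valid_i_moves(M)
        n_i <- nrow(im)
      }
      pick <- sample.int(n_f + n_i, 1L)
      M <- if (pick <= n_f) apply_f_move(M, fs[pick])
           else apply_i_move(M, im$f[pick - n_f], im$mask[pick - n_f])
    }
    M
  })
}
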