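#' Sketch a sequence with a context-free scheme
#'
#' A context-free sketching scheme (context length c = k, as in syncmers)
#' is the indicator function of its set of selected k-mers: position `i`
#' of `S` is selected iff the k-mer starting there is in `M`. When `M` is
#' a decycling set the scheme has a window guarantee equal to `M`'s
#' remaining path length.
#'
#' @param M a [kmer_set()] — the scheme's selected set.
#' @param S a symbol string over the space's alphabet, length at least k.
#' @return list of class `sketch_result`: `positions` (sorted 1-based
#'   start positions of selected k-mers) and `n_positions` (number of
#'   k-mer start positions, `nchar(S) - k + 1`).
#' @examples
#' sp <- kmer_space(2, 2)
#' sketch_sequence(kmer_set(c("00", "01", "11"), sp), "0101")$positions
#' @export
sketch_sequence <- function(M, S) {
  check_kmer_set(M)
  sp <- M$space
  k <- sp$k
  n <- nchar(S)
  if (n < k) err_input("sequence shorter than k")
  codes <- rolling_codes(S, sp)
  structure(list(positions = which(codes %in% M$members),
                 n_positions = n - k + 1L),
            class = "sketch_result")
}

# codes of all k-mers of S, by rolling update
rolling_codes <- function(S, space) {
  ch <- strsplit(S, "", fixed = TRUE)[[1]]
  v <- match(ch, as.character(0:(space$sigma - 1L))) - 1L
  if (space$sigma == 4L) {
    alt <- match(toupper(ch), dna_letters) - 1L
    v[is.na(v)] <- alt[is.na(v)]
  }
  if (anyNA(v))
    err_input("illegal symbol at position ", which(is.na(v))[1])
  k <- space$k
  n <- length(v)
  codes <- integer(n - k + 1L)
  code <- 0L
  for (i in seq_len(n)) {
    code <- if (i <= k) code * space$sigma + v[i]
            else (code %% space$n_words) * space$sigma + v[i]
    if (i >= k) codes[i - k + 1L] <- code
  }
  codes
}

#' Maximum selection gap of a sketch
#'
#' The longest run of consecutive unselected k-mer start positions,
#' counting runs at both ends; a sequence with nothing selected returns
#' its number of k-mer positions. Gaps are measured in k-mer start
#' positions (not symbols), matching the windows-of-consecutive-k-mers
#' convention under which the window guarantee equals the remaining path
#' length.
#'
#' @param result a [sketch_sequence()] result.
#' @return integer.
#' @export
max_gap <- function(result) {
  if (!inherits(result, "sketch_result")) err_input("expected sketch_result")
  sel <- rep(FALSE, result$n_positions)
  sel[result$positions] <- TRUE
  r <- rle(sel)
  gaps <- r$lengths[!r$values]
  if (length(gaps)) max(gaps) else 0L
}

#' Empirically verify the window guarantee of a decycling set
#'
#' Sketches seeded random sequences (and optionally all sequences of a
#' given length) with the context-free scheme of `M` and asserts that no
#' gap exceeds the vertex-count remaining path length of `M`: a run of p
#' unselected positions is a p-vertex walk in \eqn{D_k \setminus M},
#' and walks in a DAG are paths. The sequence spelled by a witness
#' longest path is always included, so the reported maximum gap attains
#' the bound whenever that sequence's flanks add no selection — with
#' exhaustive coverage the bound is tight.
#'
#' A gap above the bound would falsify either the remaining-path-length
#' computation or the decycling check and raises an invariant error.
#'
#' @param M a decycling [kmer_set()]; checked (precondition).
#' @param n_sequences number of random sequences.
#' @param length length of each random sequence, at least k.
#' @param seed RNG seed.
#' @param exhaustive_length also sketch all `sigma^L` sequences of this
#'   length (guarded; `NULL` to skip).
#' @return list: `max_gap_observed`, `rpl` (vertex-count bound),
#'   `n_sequences`, `seed`.
#' @examples
#' sp <- kmer_space(2, 4)
#' verify_window_guarantee(mykkeltveit_set(sp), n_sequences = 20,
#'                         length = 50, seed = 1)$max_gap_observed
#' @export
verify_window_guarantee <- function(M, n_sequences = 100L, length = 200L,
                                    seed = 1L, exhaustive_length = NULL) {
  check_kmer_set(M)
  if (!is_decycling(M)) err_input("M is not a decycling set")
  sp <- M$space
  if (length < sp$k) err_input("sequence length must be at least k")
  bound <- remaining_path_length(M, convention = "vertices")
  observed <- 0L
  check_seq <- function(S) {
    g <- max_gap(sketch_sequence(M, S))
    if (g > bound)
      err_invariant("gap ", g, " exceeds the remaining path length ", bound)
    if (g > observed) observed <<- g
  }
  # the witness path spells a sequence attaining the bound
  wit <- longest_remaining_path(M)
  if (base::length(wit)) check_seq(spell_path(wit, sp))  # `length` is an arg
  with_seed(seed, {
    for (i in seq_len(n_sequences)) {
      S <- paste(sample.int(sp$sigma, length, replace = TRUE) - 1L,
                 collapse = "")
      check_seq(S)
    }
  })
  if (!is.null(exhaustive_length)) {
    n_seq <- sp$sigma^as.numeric(exhaustive_length)
    if (n_seq > 2^20) err_resource("exhaustive check refused above 2^20 sequences")
    for (x in 0:(n_seq - 1L)) {
      check_seq(decode_word(x, sp, exhaustive_length))
    }
  }
  list(max_gap_observed = observed, rpl = bound,
       n_sequences = n_sequences, seed = seed)
}

# sequence spelled by a de Bruijn path (k-mer codes in order)
spell_path <- function(codes, space) {
  first <- decode_kmers(codes[1], space)
  rest <- vapply(codes[-1], function(u) {
    as.character(u %% space$sigma)
  }, "")
  paste0(first, paste(rest, collapse = ""))
}

#' Positional-minimum (syncmer-like) selected sets
#'
#' The open-syncmer family selects a k-mer when its smallest s-mer
#' (leftmost on ties, lexicographic on codes) sits at a masked position.
#' With the first mask bit set — the variant built here, mask bit 1 only —
#' the selected set is decycling: a run of unselected k-mers forms a
#' strictly decreasing chain of minimal s-mers, which must end. The
#' resulting set is generally far larger than an MDS and its remaining
#' path can approach \eqn{\sigma^{k-1}}, illustrating that a weak window
#' guarantee survives even in much bigger decycling sets.
#'
#' @param space a [kmer_space()].
#' @param s s-mer length, `1 <= s <= k`.
#' @return a [kmer_set()] of the k-mers whose minimal s-mer is at
#'   position 1.
#' @examples
#' sp <- kmer_space(2, 3)
#' print(syncmer_set(sp, 1))  # {000, 001, 010, 011, 111}
#' @export
syncmer_set <- function(space, s) {
  s <- as.integer(s)
  if (is.na(s) || s < 1L || s > space$k) err_input("s must be in [1, k]")
  check_enumeration_size(space)
  n_s <- space$sigma^as.numeric(s)
  sel <- vapply(0:(space$n_kmers - 1L), function(u) {
    smers <- integer(space$k - s + 1L)
    v <- u
    # s-mer at position i is floor(u / sigma^(k - s - i + 1)) mod sigma^s
    for (i in (space$k - s + 1L):1L) {
      smers[i] <- v %% n_s
      v <- v %/% space$sigma
    }
    which.min(smers) == 1L
  }, NA)
  kmer_set(which(sel) - 1L, space)
}
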