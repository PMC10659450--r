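#' Companion pattern of a word against a set
#'
#' Classifies, for each letter `a`, how the companions of the word `f`
#' meet `M`: `"L"` if only the left companion `af` is in `M`, `"R"` if
#' only the right companion `fa` is, `"B"` if `f` is a homopolymer
#' \eqn{a^{k-1}} and the shared k-mer \eqn{a^k} is in `M` (it counts as
#' both companion kinds), `"D"` if both `af` and `fa` are in `M` with
#' `af != fa`, and `"N"` if neither is.
#'
#' An all-`L` pattern (with `B` folding into both sides) means the F-move
#' at `f` is valid; a mixture of `L` and `R` with no `N` means an I-move
#' is valid.
#'
#' @param M a [kmer_set()].
#' @param f integer word code in `[0, sigma^(k-1))`.
#' @return character vector of length `sigma`, one tag per letter.
#' @examples
#' sp <- kmer_space(2, 2)
#' companion_pattern(kmer_set(c("00", "01", "11"), sp), 1)  # letter0 L, letter1 B
#' @export
companion_pattern <- function(M, f) {
  check_kmer_set(M)
  sp <- M$space
  check_word(f, sp)
  h <- homopolymer_letter(f, sp)
  vapply(0:(sp$sigma - 1L), function(a) {
    if (!is.na(h) && a == h) {
      return(if (homopolymer_kmer(a, sp) %in% M$members) "B" else "N")
    }
    l <- (a * sp$n_words + f) %in% M$members
    r <- (f * sp$sigma + a) %in% M$members
    if (l && r) "D" else if (l) "L" else if (r) "R" else "N"
  }, "")
}

#' Valid F-moves and RF-moves
#'
#' An F-move at word `f` is valid in `M` when `M` contains all left
#' companions of `f`; applying it swaps them for the right companions,
#' \eqn{fM = (M \setminus lc(f)) \cup rc(f)}. The RF-move is the inverse.
#' Both preserve set size, the one-per-orbit (PCR set) property, the
#' decycling property, and every cycle's hitting number: an MDS maps to an
#' MDS in the same component of the MDS graph. Every MDS admits at least
#' one valid F-move and one valid RF-move.
#'
#' For a homopolymer word \eqn{f = a^{k-1}} the shared k-mer \eqn{a^k} is
#' removed with the left companions and re-added with the right
#' companions, so it stays in the result.
#'
#' @param M a [kmer_set()].
#' @param f integer word code.
#' @return `valid_f_moves()` / `valid_rf_moves()`: integer vector of word
#'   codes; `apply_f_move()` / `apply_rf_move()`: a new [kmer_set()]
#'   (inputs are never mutated).
#' @examples
#' sp <- kmer_space(2, 2)
#' M <- kmer_set(c("00", "01", "11"), sp)
#' valid_f_moves(M)                      # f = "1"
#' print(apply_f_move(M, 1))             # {00, 10, 11}
#' @export
valid_f_moves <- function(M) {
  check_kmer_set(M)
  sp <- M$space
  fs <- 0:(sp$n_words - 1L)
  keep <- vapply(fs, function(f) all(left_companions(f, sp) %in% M$members),
                 NA)
  fs[keep]
}

#' @rdname valid_f_moves
#' @export
valid_rf_moves <- function(M) {
  check_kmer_set(M)
  sp <- M$space
  fs <- 0:(sp$n_words - 1L)
  keep <- vapply(fs, function(f) all(right_companions(f, sp) %in% M$members),
                 NA)
  fs[keep]
}

#' @rdname valid_f_moves
#' @export
apply_f_move <- function(M, f) {
  check_kmer_set(M)
  sp <- M$space
  check_word(f, sp)
  lc <- left_companions(f, sp)
  missing <- setdiff(lc, M$members)
  if (length(missing))
    err_input("F-move ", f, " is not valid: missing left companions ",
              paste(decode_kmers(missing, sp), collapse = ", "))
  kmer_set(union(setdiff(M$members, lc), right_companions(f, sp)), sp)
}

#' @rdname valid_f_moves
#' @export
apply_rf_move <- function(M, f) {
  check_kmer_set(M)
  sp <- M$space
  check_word(f, sp)
  rc <- right_companions(f, sp)
  missing <- setdiff(rc, M$members)
  if (length(missing))
    err_input("RF-move ", f, " is not valid: missing right companions ",
              paste(decode_kmers(missing, sp), collapse = ", "))
  kmer_set(union(setdiff(M$members, rc), left_companions(f, sp)), sp)
}

# bit of letter a (0-based) in an I-move mask
mask_bit <- function(mask, a) bitwAnd(mask, bitwShiftL(1L, a)) != 0L

#' Valid I-moves
#'
#' An I-move ("incomplete F-move") `f|m` is valid when `M` contains a
#' mixture of left and right companions of `f`: for every letter `a`,
#' either `af` or `fa` is in `M`, with at least one of each kind. The mask
#' `m` records the pre-move state, bit `a` set iff `af` is in `M`; the
#' move pushes exactly those left companions to the right,
#' \eqn{(M \setminus \{af : m_a = 1\}) \cup \{fa : m_a = 1\}}. (Under this
#' convention the full mask coincides with the F-move and the zero mask
#' with the RF-move; both are excluded from the I-move masks
#' `1..2^sigma-2`.) For a homopolymer word \eqn{f = a^{k-1}}, the bit of
#' letter `a` is pinned to 1 (\eqn{a^k} is both companion kinds and is
#' never moved) and a mixture is required among the remaining letters, so
#' only \eqn{2^{\sigma-1}-2} masks are admissible — none at `sigma = 2`.
#'
#' I-moves preserve MDS-ness but, unlike F-moves, change the cycle
#' signature: applying one always lands in a different component of the
#' MDS graph.
#'
#' For a given `f` and set, at most one mask can be valid (the mask is
#' read off the membership pattern), so `valid_i_moves()` returns at most
#' one row per word.
#'
#' @param M a [kmer_set()].
#' @param f integer word code.
#' @param mask integer in `[1, 2^sigma - 2]`, bit `a` set iff `af` is in
#'   `M` before the move.
#' @return `valid_i_moves()`: a data frame with integer columns `f` and
#'   `mask`, sorted by `(f, mask)`; `apply_i_move()`: a new [kmer_set()].
#' @examples
#' sp <- kmer_space(2, 5)
#' nrow(valid_i_moves(mykkeltveit_set(sp)))  # 0: no I-move exists at (2,5)
#' @export
valid_i_moves <- function(M) {
  check_kmer_set(M)
  sp <- M$space
  out_f <- integer(0)
  out_m <- integer(0)
  for (f in 0:(sp$n_words - 1L)) {
    mv <- i_move_at(M, f)
    if (!is.null(mv)) {
      out_f <- c(out_f, f)
      out_m <- c(out_m, mv)
    }
  }
  data.frame(f = out_f, mask = out_m)
}

# mask of the valid I-move at word f, or NULL
i_move_at <- function(M, f) {
  sp <- M$space
  pat <- companion_pattern(M, f)
  if (any(pat == "N")) return(NULL)
  if (any(pat == "D")) {
    # both af and fa in M with every letter covered cannot happen in an
    # MDS (it would contradict minimality); flag it rather than guess
    if (is_pcr_set(M) && is_decycling(M))
      err_invariant("double companion with full coverage in an MDS at word ",
                    f)
    return(NULL)
  }
  h <- homopolymer_letter(f, sp)
  if (!is.na(h)) {
    rest <- pat[setdiff(seq_along(pat), h + 1L)]
    if (all(rest == "L") || all(rest == "R")) return(NULL)  # F / RF
    mask <- sum(bitwShiftL(1L, which(pat %in% c("L", "B")) - 1L))
  } else {
    if (all(pat == "L") || all(pat == "R")) return(NULL)
    mask <- sum(bitwShiftL(1L, which(pat == "L") - 1L))
  }
  as.integer(mask)
}

#' @rdname valid_i_moves
#' @export
apply_i_move <- function(M, f, mask) {
  check_kmer_set(M)
  sp <- M$space
  check_word(f, sp)
  expected <- i_move_at(M, f)
  if (is.null(expected) || expected != mask)
    err_input("I-move ", f, "|", mask, " is not valid in this set")
  h <- homopolymer_letter(f, sp)
  letters <- 0:(sp$sigma - 1L)
  moved <- letters[mask_bit(mask, letters)]
  if (!is.na(h)) moved <- setdiff(moved, h)  # a^k is never moved
  kmer_set(union(setdiff(M$members, moved * sp$n_words + f),
                 f * sp$sigma + moved), sp)
}
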