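#' K-mer space: alphabet size and word length
#'
#' A `kmer_space` fixes the alphabet size `sigma` and word length `k` and
#' owns the encoding conventions for the de Bruijn graph \eqn{D_k} whose
#' nodes are all \eqn{\sigma^k} k-mers and whose edges are the
#' suffix-prefix overlaps \eqn{u[2..k] = v[1..k-1]}. K-mers are represented
#' as big-endian base-`sigma` integer codes (leftmost symbol most
#' significant), so successor and rotation arithmetic is O(1) and
#' "lexicographically smallest" coincides with "smallest code".
#'
#' Alphabet symbols are the digits `0..sigma-1`; for `sigma = 4` the DNA
#' letters are accepted and emitted with `A=0, C=1, G=2, T=3`.
#'
#' @param sigma integer alphabet size, at least 2.
#' @param k integer word length, at least 2. `sigma^k` must fit in the
#'   exact-integer range of a double.
#' @return An object of class `kmer_space` with fields `sigma`, `k`,
#'   `n_kmers` (\eqn{\sigma^k}) and `n_words` (\eqn{\sigma^{k-1}}, the
#'   number of (k-1)-mer "words" that index companion sets and moves).
#' @examples
#' sp <- kmer_space(2, 4)
#' sp$n_kmers
#' @export
kmer_space <- function(sigma, k) {
  sigma <- as.integer(sigma)
  k <- as.integer(k)
  if (length(sigma) != 1L || is.na(sigma) || sigma < 2L)
    err_input("sigma must be a single integer >= 2")
  if (length(k) != 1L || is.na(k) || k < 2L)
    err_input("k must be a single integer >= 2")
  n <- sigma^as.numeric(k)
  if (n > 2^31 - 1) err_input("sigma^k = ", n, " exceeds the integer range")
  structure(list(sigma = sigma, k = k,
                 n_kmers = as.integer(n),
                 n_words = as.integer(n / sigma)),
            class = "kmer_space")
}

#' @export
print.kmer_space <- function(x, ...) {
  cat(sprintf("<kmer_space sigma=%d k=%d: %d k-mers, %d words>\n",
              x$sigma, x$k, x$n_kmers, x$n_words))
  invisible(x)
}

dna_letters <- c("A", "C", "G", "T")

#' Encode and decode k-mers
#'
#' `encode_kmers()` turns symbol strings into integer codes,
#' `decode_kmers()` inverts it. Strings use the digit alphabet
#' `0..sigma-1`; for `sigma = 4`, `ACGT` (upper or lower case) is also
#' accepted, and `decode_kmers(..., dna = TRUE)` emits letters.
#'
#' @param x character vector of length-`k` strings.
#' @param space a [kmer_space()].
#' @return `encode_kmers()`: integer codes in `[0, sigma^k)`;
#'   `decode_kmers()`: character vector.
#' @examples
#' sp <- kmer_space(2, 4)
#' encode_kmers("1011", sp)  # 11
#' decode_kmers(11, sp)
#' @export
encode_kmers <- function(x, space) {
  vapply(x, function(s) encode_word(s, space, space$k), 0L, USE.NAMES = FALSE)
}

# shared by k-mer and (k-1)-mer parsing
encode_word <- function(s, space, len) {
  if (is.na(s) || nchar(s) != len)
    err_input("expected a string of length ", len, ", got \"", s, "\"")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  v <- match(ch, as.character(0:(space$sigma - 1L))) - 1L
  if (space$sigma == 4L) {
    alt <- match(toupper(ch), dna_letters) - 1L
    v[is.na(v)] <- alt[is.na(v)]
  }
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    err_input("illegal symbol '", ch[bad], "' at position ", bad,
              " for sigma = ", space$sigma)
  }
  code <- 0
  for (d in v) code <- code * space$sigma + d
  as.integer(code)
}

#' @param codes integer vector of k-mer codes.
#' @param dna emit `ACGT` instead of digits (only for `sigma = 4`).
#' @rdname encode_kmers
#' @export
decode_kmers <- function(codes, space, dna = FALSE) {
  vapply(codes, function(u) decode_word(u, space, space$k, dna), "",
         USE.NAMES = FALSE)
}

decode_word <- function(u, space, len, dna = FALSE) {
  if (is.na(u) || u < 0 || u >= space$sigma^as.numeric(len))
    err_input("code ", u, " out of range for a length-", len, " word")
  d <- integer(len)
  for (i in len:1) {
    d[i] <- u %% space$sigma
    u <- u %/% space$sigma
  }
  if (dna && space$sigma == 4L) paste(dna_letters[d + 1L], collapse = "")
  else paste(d, collapse = "")
}

#' De Bruijn graph neighborhood and rotation
#'
#' `kmer_successors()` returns the `sigma` k-mers that follow `u` by one
#' symbol (suffix-prefix overlap), `kmer_predecessors()` the `sigma` that
#' precede it, and `kmer_rotate()` the left cyclic rotation
#' \eqn{u_1 u_2 \ldots u_k \to u_2 \ldots u_k u_1}, which is always one of
#' the successors.
#'
#' @param u integer k-mer code (vectorized for `kmer_rotate`).
#' @param space a [kmer_space()].
#' @return integer codes.
#' @examples
#' sp <- kmer_space(2, 4)
#' decode_kmers(kmer_successors(encode_kmers("1010", sp), sp), sp)
#' @export
kmer_successors <- function(u, space) {
  (u %% space$n_words) * space$sigma + 0:(space$sigma - 1L)
}

#' @rdname kmer_successors
#' @export
kmer_predecessors <- function(u, space) {
  0:(space$sigma - 1L) * space$n_words + u %/% space$sigma
}

#' @rdname kmer_successors
#' @export
kmer_rotate <- function(u, space) {
  (u %% space$n_words) * space$sigma + u %/% space$n_words
}

#' Pure cycling registers (conjugacy classes)
#'
#' A pure cycling register (PCR) is the orbit of a k-mer under cyclic
#' rotation, a cycle of \eqn{D_k}. The PCRs partition the k-mers; the
#' number of orbits is the necklace count
#' \eqn{\frac{1}{k}\sum_{d\mid k}\varphi(d)\,\sigma^{k/d}}.
#'
#' `pcr_of()` returns one orbit in rotation order starting from its
#' smallest member; `enumerate_pcrs()` the full partition (orbits ordered
#' by smallest member); `count_pcrs()` the closed-form count;
#' `count_pcr_sets()` the exact number of sets with one k-mer per orbit
#' (the product of orbit sizes), returned as a double since it overflows
#' integers quickly.
#'
#' @param u integer k-mer code.
#' @param space a [kmer_space()].
#' @return See details above. `enumerate_pcrs()` returns a list with
#'   `orbits` (list of integer vectors) and `index` (integer vector mapping
#'   code + 1 to orbit id).
#' @examples
#' sp <- kmer_space(2, 4)
#' decode_kmers(pcr_of(encode_kmers("1011", sp), sp), sp)
#' count_pcrs(sp)       # 6 binary 4-necklaces
#' count_pcr_sets(sp)   # 128
#' @export
pcr_of <- function(u, space) {
  orb <- u
  v <- kmer_rotate(u, space)
  while (v != u) {
    orb <- c(orb, v)
    v <- kmer_rotate(v, space)
  }
  m <- which.min(orb)
  if (m > 1L) orb <- c(orb[m:length(orb)], orb[1:(m - 1L)])
  orb
}

#' @rdname pcr_of
#' @export
enumerate_pcrs <- function(space) {
  check_enumeration_size(space)
  index <- integer(space$n_kmers)
  orbits <- list()
  for (u in 0:(space$n_kmers - 1L)) {
    if (index[u + 1L] != 0L) next
    orb <- pcr_of(u, space)
    orbits[[length(orbits) + 1L]] <- orb
    index[orb + 1L] <- length(orbits)
  }
  stopifnot(length(orbits) == count_pcrs(space))
  list(orbits = orbits, index = index)
}

euler_phi <- function(n) {
  r <- n
  p <- 2
  while (p * p <= n) {
    if (n %% p == 0) {
      while (n %% p == 0) n <- n %/% p
      r <- r - r %/% p
    }
    p <- p + 1
  }
  if (n > 1) r <- r - r %/% n
  r
}

#' @rdname pcr_of
#' @export
count_pcrs <- function(space) {
  k <- space$k
  d <- which(k %% seq_len(k) == 0)
  total <- sum(vapply(d, function(dd) {
    euler_phi(dd) * space$sigma^as.numeric(k / dd)
  }, 0))
  as.integer(total / k)
}

#' @rdname pcr_of
#' @export
count_pcr_sets <- function(space) {
  part <- enumerate_pcrs(space)
  prod(vapply(part$orbits, length, 0L))
}

#' Companion sets of a (k-1)-mer word
#'
#' For a word \eqn{f \in \Sigma^{k-1}}, the left companions are
#' \eqn{lc(f) = \{af \mid a \in \Sigma\}} and the right companions
#' \eqn{rc(f) = \{fa \mid a \in \Sigma\}}; they induce a complete bipartite
#' \eqn{K_{\sigma,\sigma}} of de Bruijn edges. The two sets are disjoint
#' unless `f` is a homopolymer \eqn{a^{k-1}}, in which case they share
#' exactly the homopolymer k-mer \eqn{a^k}.
#'
#' @param f integer word code in `[0, sigma^(k-1))`.
#' @param space a [kmer_space()].
#' @return integer k-mer codes, ascending.
#' @examples
#' sp <- kmer_space(2, 4)
#' decode_kmers(left_companions(3, sp), sp)  # f = "011"
#' @export
left_companions <- function(f, space) {
  check_word(f, space)
  0:(space$sigma - 1L) * space$n_words + f
}

#' @rdname left_companions
#' @export
right_companions <- function(f, space) {
  check_word(f, space)
  f * space$sigma + 0:(space$sigma - 1L)
}

check_word <- function(f, space) {
  if (length(f) != 1L || is.na(f) || f < 0 || f >= space$n_words)
    err_input("word code must lie in [0, ", space$n_words, ")")
  invisible(TRUE)
}

# letter a if f is the homopolymer word a^(k-1), else NA
homopolymer_letter <- function(f, space) {
  rep1 <- (space$n_words - 1L) %/% (space$sigma - 1L)
  if (f %% rep1 == 0L && f %/% rep1 < space$sigma) f %/% rep1 else NA_integer_
}

# code of the homopolymer k-mer a^k
homopolymer_kmer <- function(a, space) {
  as.integer(a * (space$n_kmers - 1L) %/% (space$sigma - 1L))
}
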