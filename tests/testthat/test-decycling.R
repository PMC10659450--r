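test_that("is_decycling matches the definition and the igraph oracle", {
  sp3 <- kmer_space(2, 3)
  expect_true(is_decycling(kmer_set(0:7, sp3)))
  expect_false(is_decycling(kmer_set(integer(), sp3)))
  # smallest-rotation representatives leave the cycle 010 -> 101 -> 010
  expect_false(is_decycling(kmer_set(c("000", "001", "011", "111"), sp3)))

  set.seed(42)
  for (k in c(4, 5)) {
    sp <- kmer_space(2, k)
    for (i in 1:25) {
      S <- random_pcr_set(sp)
      expect_identical(is_decycling(S),
                       h_oracle_is_decycling(S$members, sp))
    }
  }
})

test_that("is_pcr_set detects one-per-orbit membership", {
  sp <- kmer_space(2, 2)
  expect_true(is_pcr_set(kmer_set(c("00", "01", "11"), sp)))
  expect_false(is_pcr_set(kmer_set(c("00", "01", "10", "11"), sp)))
  expect_false(is_pcr_set(kmer_set(c("00", "11"), sp)))
  # every MDS is a PCR set, exhaustively for k <= 5
  for (k in 2:5) {
    for (M in h_all_mds(k)) expect_true(is_pcr_set(M))
  }
})

test_that("remaining path length matches the exhaustive-DFS oracle", {
  sp <- kmer_space(2, 4)
  expect_identical(remaining_path_length(kmer_set(0:15, sp)), 0L)
  expect_error(remaining_path_length(kmer_set(integer(), sp)),
               "graph has a cycle")

  set.seed(7)
  delta <- rpl_calibration_offset()
  for (k in 4:5) {
    spk <- kmer_space(2, k)
    for (i in 1:15) {
      D <- h_random_decycling_set(spk)
      expect_identical(remaining_path_length(D, convention = "vertices"),
                       h_oracle_rpl_vertices(D$members, spk))
      expect_identical(remaining_path_length(D),
                       h_oracle_rpl_vertices(D$members, spk) - delta)
    }
  }
})

test_that("witness paths are maximal, valid, and start/end at F/RF-moves", {
  sp <- kmer_space(2, 4)
  expect_length(longest_remaining_path(kmer_set(0:15, sp)), 0)
  for (k in 4:5) {
    spk <- kmer_space(2, k)
    for (M in h_all_mds(k)) {
      p <- longest_remaining_path(M)
      expect_identical(length(p),
                       remaining_path_length(M, convention = "vertices"))
      expect_length(intersect(p, M$members), 0)
      if (length(p) > 1) {
        for (i in seq_len(length(p) - 1))
          expect_true(p[i + 1] %in% kmer_successors(p[i], spk))
      }
      # first vertex lies in rc(f) of a valid F-move, last in lc(f') of a
      # valid RF-move
      f_start <- p[1] %/% spk$sigma
      expect_true(f_start %in% valid_f_moves(M))
      f_end <- p[length(p)] %% spk$n_words
      expect_true(f_end %in% valid_rf_moves(M))
    }
  }
})

test_that("cycle enumeration is exact at k=2 and edge-valid at k=3", {
  sp <- kmer_space(2, 2)
  cyc <- enumerate_cycles(sp)
  expect_identical(lapply(cyc, function(cy) decode_kmers(cy, sp)),
                   list("00", "11", c("01", "10"), c("00", "01", "10"),
                        c("01", "11", "10"), c("00", "01", "11", "10")))
  sp3 <- kmer_space(2, 3)
  cyc3 <- enumerate_cycles(sp3)
  for (cy in cyc3) {
    nxt <- c(cy[-1], cy[1])
    for (i in seq_along(cy))
      expect_true(nxt[i] %in% kmer_successors(cy[i], sp3))
  }
  expect_identical(anyDuplicated(vapply(cyc3, paste, "", collapse = ",")), 0L)
  # every PCR orbit appears among the cycles
  canon <- vapply(cyc3, paste, "", collapse = ",")
  for (orb in enumerate_pcrs(sp3)$orbits)
    expect_true(paste(orb, collapse = ",") %in% canon)
  expect_error(enumerate_cycles(kmer_space(2, 6)),
               class = "decyclr_resource_error")
})

test_that("hitting numbers and signatures behave as the theory predicts", {
  sp <- kmer_space(2, 2)
  M <- kmer_set(c("00", "01", "11"), sp)
  cyc <- enumerate_cycles(sp)
  expect_identical(cycle_signature(M, cyc), c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(hitting_number(M, encode_kmers(c("01", "11", "10"), sp)), 2L)
  expect_error(hitting_number(M, encode_kmers(c("00", "11"), sp)),
               class = "decyclr_input_error")

  for (k in 2:4) {
    spk <- kmer_space(2, k)
    cyck <- enumerate_cycles(spk)
    ham <- cyck[lengths(cyck) == spk$n_kmers]
    expect_gte(length(ham), 1)
    part <- enumerate_pcrs(spk)
    for (M in h_all_mds(k)) {
      sig <- cycle_signature(M, cyck)
      expect_true(all(sig >= 1L))
      # PCR orbits are hit exactly once, Hamiltonian cycles |M| times
      for (orb in part$orbits) expect_identical(hitting_number(M, orb), 1L)
      expect_identical(hitting_number(M, ham[[1]]), length(M$members))
    }
  }
})

test_that("a non-decycling PCR set misses some cycle entirely outside it", {
  # cross-check of is_decycling against signatures at k <= 4: a PCR set
  # that is not decycling leaves a cycle with hitting number 0
  for (k in 3:4) {
    spk <- kmer_space(2, k)
    cyck <- enumerate_cycles(spk)
    part <- enumerate_pcrs(spk)
    set.seed(k)
    for (i in 1:20) {
      S <- random_pcr_set(spk)
      sig <- cycle_signature(S, cyck)
      expect_identical(is_decycling(S), all(sig >= 1L))
    }
  }
})

test_that("brute force reproduces the exhaustive MDS counts", {
  expect_length(h_all_mds(2), 2)
  expect_length(h_all_mds(3), 4)
  expect_length(h_all_mds(4), 30)
  expect_length(h_all_mds(5), 28)
  # MDS fraction at (2,4), computed not assumed
  expect_identical(count_pcr_sets(kmer_space(2, 4)), 128)
  expect_identical(length(h_all_mds(4)) / count_pcr_sets(kmer_space(2, 4)),
                   30 / 128)
  for (M in h_all_mds(4)) {
    expect_true(is_pcr_set(M))
    expect_true(is_decycling(M))
    expect_length(M$members, count_pcrs(kmer_space(2, 4)))
  }
  expect_error(brute_force_mds(kmer_space(2, 10)),
               class = "decyclr_resource_error")
})

test_that("PCR-set counts are exact products of orbit sizes", {
  expect_identical(count_pcr_sets(kmer_space(2, 2)), 2)
  expect_identical(count_pcr_sets(kmer_space(2, 4)), 128)
  n8 <- count_pcr_sets(kmer_space(2, 8))
  expect_gt(n8, 1e29)
  expect_lt(n8, 3e29)
})

test_that("the path-length convention calibrates to offset 0 at k=4", {
  expect_identical(rpl_calibration_offset(), 0L)
  verts <- vapply(h_all_mds(4), remaining_path_length,
                  0L, convention = "vertices")
  expect_identical(range(verts), c(5L, 7L))
})
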