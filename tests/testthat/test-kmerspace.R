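test_that("encoding is big-endian base-sigma and decode inverts it", {
  sp2 <- kmer_space(2, 4)
  expect_identical(encode_kmers("0000", sp2), 0L)
  expect_identical(encode_kmers("1011", sp2), 11L)
  sp4 <- kmer_space(4, 4)
  expect_identical(encode_kmers("ACGT", sp4), 27L)
  expect_identical(encode_kmers("acgt", sp4), 27L)
  expect_identical(decode_kmers(27L, sp4, dna = TRUE), "ACGT")

  set.seed(1)
  for (sp in list(sp2, sp4, kmer_space(3, 5))) {
    s <- vapply(1:25, function(i) {
      paste(sample(0:(sp$sigma - 1L), sp$k, replace = TRUE), collapse = "")
    }, "")
    expect_identical(decode_kmers(encode_kmers(s, sp), sp), s)
  }

  expect_error(encode_kmers("012", sp2), class = "decyclr_input_error")
  expect_error(encode_kmers("0000", kmer_space(2, 3)),
               class = "decyclr_input_error")
  err <- tryCatch(encode_kmers("0020", sp2), condition = identity)
  expect_match(conditionMessage(err), "position 3")
})

test_that("the graph is sigma-regular with consistent successors/predecessors", {
  for (args in list(c(2, 5), c(2, 7), c(4, 3), c(4, 4))) {
    sp <- kmer_space(args[1], args[2])
    for (u in 0:(sp$n_kmers - 1L)) {
      succ <- kmer_successors(u, sp)
      expect_length(succ, sp$sigma)
      expect_length(kmer_predecessors(u, sp), sp$sigma)
    }
    # edge symmetry, sampled
    us <- sample(0:(sp$n_kmers - 1L), 20)
    for (u in us) {
      for (v in kmer_successors(u, sp))
        expect_true(u %in% kmer_predecessors(v, sp))
    }
  }
  sp <- kmer_space(2, 4)
  expect_setequal(decode_kmers(kmer_successors(encode_kmers("1010", sp), sp), sp),
                  c("0100", "0101"))
  # homopolymer self-loop
  expect_true(0L %in% kmer_successors(0L, sp))
})

test_that("rotation is a successor, has period k, matches string rotation", {
  sp <- kmer_space(2, 4)
  expect_identical(decode_kmers(kmer_rotate(encode_kmers("1011", sp), sp), sp),
                   "0111")
  expect_identical(kmer_rotate(0L, sp), 0L)
  set.seed(2)
  for (spc in list(sp, kmer_space(4, 5))) {
    us <- sample(0:(spc$n_kmers - 1L), 100, replace = TRUE)
    for (u in us) {
      v <- u
      for (i in seq_len(spc$k)) {
        expect_true(kmer_rotate(v, spc) %in% kmer_successors(v, spc))
        v <- kmer_rotate(v, spc)
      }
      expect_identical(v, u)
    }
  }
})

test_that("PCR orbits partition the k-mers and match the necklace count", {
  sp <- kmer_space(2, 4)
  orb <- pcr_of(encode_kmers("1011", sp), sp)
  expect_identical(decode_kmers(orb, sp), c("0111", "1110", "1101", "1011"))
  expect_identical(decode_kmers(pcr_of(encode_kmers("0101", sp), sp), sp),
                   c("0101", "1010"))
  expect_identical(pcr_of(15L, sp), 15L)

  part <- enumerate_pcrs(sp)
  expect_identical(sort(vapply(part$orbits, length, 0L)),
                   c(1L, 1L, 2L, 4L, 4L, 4L))
  expect_setequal(unlist(part$orbits), 0:15)
  expect_identical(length(enumerate_pcrs(kmer_space(2, 2))$orbits), 3L)
  expect_identical(length(enumerate_pcrs(kmer_space(2, 6))$orbits), 14L)

  expect_identical(count_pcrs(kmer_space(2, 2)), 3L)
  expect_identical(count_pcrs(kmer_space(2, 6)), 14L)
  expect_identical(count_pcrs(kmer_space(4, 4)), 70L)
  for (sigma in c(2L, 4L)) {
    for (k in 2:ifelse(sigma == 2, 10, 7)) {
      sp_k <- kmer_space(sigma, k)
      expect_identical(count_pcrs(sp_k),
                       length(enumerate_pcrs(sp_k)$orbits))
    }
  }
})

test_that("companion sets are correct and induce a complete bipartite K_sigma,sigma", {
  sp <- kmer_space(2, 4)
  f <- encode_kmers("0110", sp) %/% 2L  # "011" = 3
  expect_identical(f, 3L)
  expect_setequal(decode_kmers(left_companions(3L, sp), sp), c("0011", "1011"))
  expect_setequal(decode_kmers(right_companions(3L, sp), sp), c("0110", "0111"))
  # homopolymer word: overlap is exactly the homopolymer k-mer
  expect_identical(intersect(left_companions(7L, sp), right_companions(7L, sp)),
                   15L)
  expect_length(intersect(left_companions(3L, sp), right_companions(3L, sp)), 0)
  # every af -> fb is an edge
  for (fw in 0:(sp$n_words - 1L)) {
    for (u in left_companions(fw, sp))
      expect_true(all(right_companions(fw, sp) %in% kmer_successors(u, sp)))
  }
  # every non-homopolymer k-mer is in exactly one lc and one rc
  all_lc <- unlist(lapply(0:(sp$n_words - 1L), left_companions, sp))
  all_rc <- unlist(lapply(0:(sp$n_words - 1L), right_companions, sp))
  non_hom <- setdiff(0:15, c(0L, 15L))
  expect_true(all(tabulate(all_lc + 1L, 16)[non_hom + 1L] == 1L))
  expect_true(all(tabulate(all_rc + 1L, 16)[non_hom + 1L] == 1L))
})

test_that("enumeration guard refuses oversized spaces", {
  withr::local_options(decyclr.max_nodes = 2^10)
  expect_error(enumerate_pcrs(kmer_space(2, 12)),
               class = "decyclr_resource_error")
})
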