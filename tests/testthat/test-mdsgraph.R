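test_that("component enumeration at k=4 reproduces the known structure", {
  sp <- kmer_space(2, 4)
  g <- enumerate_all_components(sp)
  sizes <- vapply(g$components, `[[`, 0, "size")
  expect_length(g$components, 3)
  expect_identical(sum(sizes), 30)
  expect_identical(g$n_mds_total, 30)
  for (cp in g$components) {
    expect_length(cp$layer_sizes, 8)        # sigma^(k-1) layers
    expect_true(all(cp$layer_sizes %in% c(1, 2)))
    expect_identical(sum(cp$layer_sizes), cp$size)
    # representative is the smallest member
    keys <- apply(cp$members, 1, paste, collapse = ",")
    expect_identical(format(cp$representative), min(keys))
  }
  # exactly the brute-force MDSs, partitioned
  all_keys <- unlist(lapply(g$components, function(cp)
    apply(cp$members, 1, paste, collapse = ",")))
  expect_setequal(all_keys, vapply(h_all_mds(4), format, ""))
})

test_that("the F-move graph at k=4 is strongly connected per component with girth 8", {
  # independent oracle route: build G_MDS explicitly with igraph
  mdss <- h_all_mds(4)
  g <- h_fmove_igraph(mdss)
  comp <- igraph::components(g, mode = "strong")
  expect_equal(comp$no, 3)
  expect_equal(igraph::components(g, mode = "weak")$no, 3)
  # distances along edges advance layers by exactly 1 mod 8
  d <- igraph::distances(g, mode = "out")
  el <- igraph::as_edgelist(g)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    root <- which(comp$membership == comp$membership[a])[1]
    expect_identical((d[root, b] - d[root, a]) %% 8, 1)
  }
  # girth: shortest directed cycle through any node is 8
  self_cycles <- vapply(seq_len(igraph::vcount(g)), function(v) {
    min(1 + d[igraph::neighbors(g, v, mode = "out"), v])
  }, 0)
  expect_identical(min(self_cycles), 8)
  expect_true(all(self_cycles == 8))  # every node lies on an 8-cycle
})

test_that("component I-move lists match the brute-force sweep (k=4)", {
  sp <- kmer_space(2, 4)
  g <- enumerate_all_components(sp)
  lists <- lapply(g$components, function(cp) {
    bf <- do.call(rbind, lapply(seq_len(nrow(cp$members)), function(r)
      valid_i_moves(kmer_set(cp$members[r, ], sp))))
    bf <- unique(bf)
    bf <- bf[order(bf$f, bf$mask), , drop = FALSE]
    rownames(bf) <- NULL
    expect_identical(cp$imoves, bf)
    cp$imoves
  })
  # distinct I-move lists across the three components
  keys <- vapply(lists, function(l) paste(l$f, l$mask, collapse = ";"), "")
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("signatures are constant within and distinct across components (k=4)", {
  sp <- kmer_space(2, 4)
  cyc <- enumerate_cycles(sp)
  g <- enumerate_all_components(sp)
  sigs <- vapply(g$components, function(cp) {
    per_member <- apply(cp$members, 1, function(m)
      paste(cycle_signature(kmer_set(m, sp), cyc), collapse = ","))
    expect_identical(length(unique(per_member)), 1L)
    per_member[1]
  }, "")
  expect_identical(anyDuplicated(sigs), 0L)
})

test_that("every component I-move has a host and the complement mask jumps back", {
  sp <- kmer_space(2, 4)
  g <- enumerate_all_components(sp)
  full <- 2L^sp$sigma - 1L
  key_of_comp <- function(M) {
    # which component contains M
    which(vapply(g$components, function(cp)
      format(M) %in% apply(cp$members, 1, paste, collapse = ","), NA))
  }
  for (ci in seq_along(g$components)) {
    cp <- g$components[[ci]]
    for (i in seq_len(nrow(cp$imoves))) {
      f <- cp$imoves$f[i]; mask <- cp$imoves$mask[i]
      host <- find_mds_with_pattern(cp, f, mask)
      expect_true(is_pcr_set(host) && is_decycling(host))
      expect_identical(key_of_comp(host), ci)
      dest <- apply_i_move(host, f, mask)
      cj <- key_of_comp(dest)
      expect_false(identical(ci, cj))
      # complement mask is in the destination list and returns to source
      cmask <- bitwAnd(bitwNot(mask), full)
      dest_cp <- g$components[[cj]]
      expect_true(any(dest_cp$imoves$f == f & dest_cp$imoves$mask == cmask))
      back <- apply_i_move(find_mds_with_pattern(dest_cp, f, cmask), f, cmask)
      expect_identical(key_of_comp(back), ci)
    }
  }
  # the recorded edges are those jumps, undirected and symmetric
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
})

test_that("the traversal reproduces small-k totals and layer structure", {
  g2 <- enumerate_all_components(kmer_space(2, 2))
  expect_length(g2$components, 1)
  expect_identical(g2$n_mds_total, 2)
  g3 <- enumerate_all_components(kmer_space(2, 3))
  expect_length(g3$components, 1)
  expect_identical(g3$n_mds_total, 4)
  g5 <- enumerate_all_components(kmer_space(2, 5))
  expect_length(g5$components, 1)
  expect_identical(g5$n_mds_total, 28)
  expect_length(g5$components[[1]]$layer_sizes, 16)
  expect_true(all(g5$components[[1]]$layer_sizes %in% c(1, 2)))
  expect_identical(nrow(g5$components[[1]]$imoves), 0L)
  expect_identical(component_rpl_range(g5$components[[1]]), c(11L, 12L))
})

test_that("component RPL ranges are consistent and O(k)-narrow at k<=5", {
  for (k in 4:5) {
    g <- enumerate_all_components(kmer_space(2, k))
    for (cp in g$components) {
      rng <- component_rpl_range(cp)
      expect_lte(rng[1], rng[2])
      # attained by members
      rpls <- apply(cp$members, 1, function(m)
        remaining_path_length(kmer_set(m, kmer_space(2, k))))
      expect_identical(range(rpls), as.integer(rng))
      expect_lte(rng[2] - rng[1], k)  # observed range, narrow
    }
  }
})

test_that("enumerate_component rejects non-MDS seeds", {
  sp <- kmer_space(2, 4)
  expect_error(enumerate_component(kmer_set(0:5, sp)),
               class = "decyclr_input_error")
  S <- random_pcr_set(sp, seed = 99)
  while (is_decycling(S)) S <- random_pcr_set(sp)
  expect_error(enumerate_component(S), class = "decyclr_input_error")
  expect_error(component_i_moves(S), class = "decyclr_input_error")
})
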