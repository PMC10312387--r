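star_network <- function() {
  # center expresses 3 concept pairs with weight_families 2 each: build it
  # directly from instances via a crafted wordlist -- simpler to construct the
  # igraph by hand through the same constructor the package uses
  df <- rbind(
    data.frame(DOCULECT = "L1", FAMILY = "F1", CONCEPT = c("HUB", "A"),
               FORM = c("tolo", "tolo")),
    data.frame(DOCULECT = "L2", FAMILY = "F2", CONCEPT = c("HUB", "A"),
               FORM = c("kipa", "kipa")),
    data.frame(DOCULECT = "L3", FAMILY = "F3", CONCEPT = c("HUB", "B"),
               FORM = c("muna", "muna")),
    data.frame(DOCULECT = "L4", FAMILY = "F4", CONCEPT = c("HUB", "B"),
               FORM = c("sere", "sere")),
    data.frame(DOCULECT = "L5", FAMILY = "F5", CONCEPT = c("HUB", "C"),
               FORM = c("pani", "pani")),
    data.frame(DOCULECT = "L6", FAMILY = "F6", CONCEPT = c("HUB", "C"),
               FORM = c("rugo", "rugo")))
  buildNetwork(toy_wordlist(df), "full")
}

test_that("weighted degrees sum edge weights; isolated nodes get zero", {
  net <- star_network()
  d <- degreeVector(net, "undirected", "families")
  expect_equal(unname(d["HUB"]), 6)
  expect_equal(unname(d[c("A", "B", "C")]), c(2, 2, 2))

  # isolated concept: attested in the wordlist, no colexification
  df <- rbind(earth_world_table(),
              data.frame(DOCULECT = "German", CONCEPT = "MOON", FORM = "Mond"))
  net2 <- buildNetwork(toy_wordlist(df), "full")
  d2 <- degreeVector(net2, "undirected", "forms")
  expect_equal(unname(d2["MOON"]), 0)
})

test_that("in- and out-degrees follow edge direction in affix networks", {
  net <- buildNetwork(toy_wordlist(hand_glove_table(), lowercase = TRUE), "affix")
  din <- degreeVector(net, "in", "unweighted")
  dout <- degreeVector(net, "out", "unweighted")
  expect_equal(unname(dout[c("HAND", "SHOE", "GLOVE")]), c(1, 1, 0))
  expect_equal(unname(din[c("HAND", "SHOE", "GLOVE")]), c(0, 0, 2))
  # mode compatibility is enforced both ways
  expect_error(degreeVector(net, "undirected"), "directed")
  expect_error(degreeVector(star_network(), "in"), "directed")
})

test_that("degree conservation identities hold on generated networks", {
  for (seed in c(2, 9)) {
    gen <- generateWordlist(synthSpec(n_languages = 4, n_concepts = 25, seed = seed))
    for (wt in c("forms", "languages", "families", "unweighted")) {
      ovl <- buildNetwork(gen$wordlist, "overlap")
      d <- degreeVector(ovl, "undirected", wt)
      w <- if (wt == "unweighted") rep(1, igraph::ecount(networkGraph(ovl)))
           else igraph::edge_attr(networkGraph(ovl), paste0("weight_", wt))
      expect_equal(sum(d), 2 * sum(w), info = paste(seed, wt))

      aff <- buildNetwork(gen$wordlist, "affix")
      din <- degreeVector(aff, "in", wt)
      dout <- degreeVector(aff, "out", wt)
      wa <- if (wt == "unweighted") rep(1, igraph::ecount(networkGraph(aff)))
            else igraph::edge_attr(networkGraph(aff), paste0("weight_", wt))
      expect_equal(sum(din), sum(wa), info = paste(seed, wt))
      expect_equal(sum(dout), sum(wa), info = paste(seed, wt))
    }
  }
})

test_that("rank correlation of degree vectors behaves like Spearman's rho", {
  va <- c(A = 1, B = 2, C = 3, D = 4, E = 5)
  expect_equal(compareDegrees(va, va)$rho, 1)
  expect_equal(compareDegrees(va, rev(unname(va)) |> setNames(names(va)))$rho, -1)

  # against the rank-difference closed form: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  vb <- c(A = 2, B = 1, C = 4, D = 3, E = 5)
  d2 <- sum((rank(va) - rank(vb))^2)
  expect_equal(compareDegrees(va, vb)$rho, 1 - 6 * d2 / (5 * (5^2 - 1)))

  # ties: average ranks, i.e. Pearson correlation of the midranks
  vc <- c(A = 1, B = 1, C = 2, D = 3, E = 3)
  vd <- c(A = 3, B = 1, C = 2, D = 2, E = 5)
  expect_equal(compareDegrees(vc, vd)$rho,
               unname(cor(rank(vc), rank(vd))))

  # comparison is restricted to shared concepts and is symmetric
  ve <- c(B = 5, C = 1, D = 2, E = 9, F = 4)
  r1 <- compareDegrees(va, ve); r2 <- compareDegrees(ve, va)
  expect_equal(r1$n, 4L)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p_value, r2$p_value)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)

  expect_error(compareDegrees(c(A = 1, B = 2), c(A = 2, B = 1)), "at least 3")
})

test_that("induced subgraphs keep annotations, kind, and directedness", {
  # path A - B - C via full colexification in two languages
  df <- rbind(
    data.frame(DOCULECT = "L1", CONCEPT = c("A", "B"), FORM = c("tolo", "tolo")),
    data.frame(DOCULECT = "L2", CONCEPT = c("B", "C"), FORM = c("kipa", "kipa")))
  net <- buildNetwork(toy_wordlist(df), "full")
  expect_equal(igraph::ecount(networkGraph(net)), 2L)

  sub <- extractSubgraph(net, c("A", "C"))
  expect_s4_class(sub, "ColexNetwork")
  expect_equal(networkKind(sub), "full")
  expect_equal(igraph::vcount(networkGraph(sub)), 2L)
  expect_equal(igraph::ecount(networkGraph(sub)), 0L)

  # subgraph on all nodes reproduces the network; idempotence
  all_sub <- extractSubgraph(net, concepts(toy_wordlist(df)))
  expect_equal(edgeTable(all_sub), edgeTable(net))
  twice <- extractSubgraph(extractSubgraph(net, c("A", "B")), c("A", "B"))
  expect_equal(edgeTable(twice), edgeTable(extractSubgraph(net, c("A", "B"))))

  # single concept: 1 node, 0 edges; unknown concepts warn and come back isolated
  one <- extractSubgraph(net, "B")
  expect_equal(igraph::vcount(networkGraph(one)), 1L)
  expect_equal(igraph::ecount(networkGraph(one)), 0L)
  expect_warning(mi <- extractSubgraph(net, c("A", "ZZZ")), "ZZZ")
  expect_true("ZZZ" %in% igraph::V(networkGraph(mi))$name)
})

test_that("community detection separates weakly joined cliques deterministically", {
  # two triangles joined by a single bridge, built from full colexifications:
  # every within-clique pair is attested in 3 families, the bridge in 1
  clique_rows <- function(members, langs) {
    do.call(rbind, lapply(seq_along(langs), function(i) {
      pair <- t(combn(members, 2))[((i - 1) %% 3) + 1, ]
      data.frame(DOCULECT = langs[i], FAMILY = langs[i], CONCEPT = pair,
                 FORM = paste0("w", i, substr(members[1], 1, 1)))
    }))
  }
  df <- rbind(
    clique_rows(c("A1", "A2", "A3"), sprintf("LA%d", 1:9)),
    clique_rows(c("B1", "B2", "B3"), sprintf("LB%d", 1:9)),
    data.frame(DOCULECT = "LX", FAMILY = "LX", CONCEPT = c("A1", "B1"),
               FORM = "bridge"))
  net <- buildNetwork(toy_wordlist(df), "full")
  m <- detectCommunities(net, "infomap", seed = 4)
  expect_equal(length(unique(m)), 2L)
  expect_equal(length(unique(m[c("A1", "A2", "A3")])), 1L)
  expect_equal(length(unique(m[c("B1", "B2", "B3")])), 1L)
  expect_false(m[["A1"]] == m[["B1"]])
  # deterministic given the seed
  expect_identical(m, detectCommunities(net, "infomap", seed = 4))
  # label propagation agrees on this strongly modular toy graph
  lp <- detectCommunities(net, "label-propagation", seed = 4)
  expect_equal(length(unique(lp[c("A1", "A2", "A3")])), 1L)

  # degenerate cases: single node, edgeless network
  single <- buildNetwork(toy_wordlist(
    data.frame(DOCULECT = "L", CONCEPT = "A", FORM = "x")), "full")
  expect_equal(unique(detectCommunities(single, "infomap", seed = 1)),
               unique(1L))
  edgeless <- buildNetwork(toy_wordlist(
    data.frame(DOCULECT = "L", CONCEPT = c("A", "B", "C"),
               FORM = c("xx", "yy", "zz"))), "full")
  expect_equal(length(unique(detectCommunities(edgeless, "infomap", seed = 1))),
               3L)

  # directed affix networks are rejected
  aff <- buildNetwork(toy_wordlist(hand_glove_table(), lowercase = TRUE), "affix")
  expect_error(detectCommunities(aff, "infomap", seed = 1), "undirected")
})
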