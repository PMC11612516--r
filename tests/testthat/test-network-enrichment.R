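toy_net <- function(edges, genes = NULL, candidates = NULL) {
  interactome(edges, genes = genes, candidates = candidates)
}

test_that("interactome constructor enforces its invariants", {
  e <- data.frame(gene_a = c("b", "a"), gene_b = c("a", "c"),
                  probability = c(0.95, 0.5))
  net <- toy_net(e)
  expect_identical(net$edges$gene_a, c("a", "a"))   # canonical orientation
  expect_error(toy_net(data.frame(gene_a = "a", gene_b = "a",
                                  probability = 0.5)), "self-loops")
  expect_error(toy_net(data.frame(gene_a = c("a", "b"),
                                  gene_b = c("b", "a"),
                                  probability = c(0.5, 0.6))), "duplicate")
  expect_error(toy_net(data.frame(gene_a = "a", gene_b = "b",
                                  probability = 1.2)), "probabilities")
})

test_that("probability filter is boundary-inclusive and idempotent", {
  e <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                  probability = c(0.90, 0.899, 0.95))
  net <- toy_net(e)
  f <- filter_by_probability(net, 0.90)
  expect_setequal(paste(f$edges$gene_a, f$edges$gene_b),
                  c("a b", "b c"))
  expect_identical(filter_by_probability(f, 0.90)$edges, f$edges)
  expect_identical(f$genes, net$genes)   # universe is preserved
})

test_that("direct-interaction subgraph keeps candidate-touching edges only", {
  e <- data.frame(gene_a = c("c1", "c1", "x", "y"),
                  gene_b = c("c2", "x", "y", "z"),
                  probability = 0.95)
  net <- toy_net(e)
  sub <- direct_interaction_subgraph(net, c("c1", "c2"))
  expect_setequal(paste(sub$edges$gene_a, sub$edges$gene_b),
                  c("c1 c2", "c1 x"))
  # partner set = neighbors(candidates) \ candidates, against brute force
  nbrs <- unique(c(e$gene_b[e$gene_a %in% c("c1", "c2")],
                   e$gene_a[e$gene_b %in% c("c1", "c2")]))
  expect_setequal(partners(sub), setdiff(nbrs, c("c1", "c2")))
  # candidates touching nothing -> empty graph
  none <- direct_interaction_subgraph(net, "absent")
  expect_identical(nrow(none$edges), 0L)
})

test_that("partner pruning applies the distinct-candidate-neighbor rule", {
  # p1 links 3 candidates, p2 links 1; candidate-candidate edge persists
  e <- data.frame(gene_a = c("c1", "c1", "c2", "c3", "c2"),
                  gene_b = c("c2", "p1", "p1", "p1", "p2"),
                  probability = 0.95)
  sub <- direct_interaction_subgraph(toy_net(e), c("c1", "c2", "c3"))
  k2 <- prune_partners(sub, 2)
  expect_true("p1" %in% network_genes(k2))
  expect_false("p2" %in% network_genes(k2))
  expect_true(all(c("c1", "c2") %in% network_genes(k2)))
  # k = 1 is the identity on partners
  expect_identical(prune_partners(sub, 1)$edges, sub$edges)
  expect_error(prune_partners(sub, 0), ">= 1")
  # monotone: k+1 network is a subgraph of the k network
  for (k in 1:3) {
    ek1 <- prune_partners(sub, k + 1)$edges
    ek <- prune_partners(sub, k)$edges
    expect_true(all(paste(ek1$gene_a, ek1$gene_b) %in%
                      paste(ek$gene_a, ek$gene_b)))
  }
  # total-degree mode counts every subgraph edge of the partner
  e2 <- data.frame(gene_a = c("c1", "p1"), gene_b = c("p1", "c1x"),
                   probability = 0.95)
  sub2 <- direct_interaction_subgraph(toy_net(e2), c("c1", "c1x"))
  expect_true("p1" %in% network_genes(prune_partners(sub2, 2,
                                                     mode = "total")))
})

test_that("enrichment p equals the hypergeometric closed form", {
  genes <- sprintf("g%02d", 1:10)
  expect_equal(enrichment_fisher(genes[1:4], genes[1:4], 10),
               1 / choose(10, 4))
  # zero overlap in a small network: no evidence of enrichment
  expect_gte(enrichment_fisher(genes[1:2], genes[5:7], 10), 0.5)
  expect_error(enrichment_fisher(genes, genes, 5), "universe size")
  # oracle: one-sided fisher.test on random instances
  withr::with_seed(88, {
    for (i in 1:25) {
      N <- sample(10:40, 1)
      uni <- sprintf("u%02d", 1:N)
      net <- sample(uni, sample(2:(N - 2), 1))
      cand <- sample(uni, sample(2:(N - 2), 1))
      x <- length(intersect(net, cand))
      tab <- matrix(c(x, length(net) - x, length(cand) - x,
                      N - length(net) - length(cand) + x), 2, 2)
      expect_equal(enrichment_fisher(net, cand, N),
                   stats::fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("degree sweep concentrates a star toy and handles empties", {
  # one partner linked to 5 candidates plus noise partners seen once
  e <- data.frame(
    gene_a = c(paste0("c", 1:5), "c1", "c2"),
    gene_b = c(rep("hub", 5), "noise1", "noise2"),
    probability = 0.95)
  genes <- c(paste0("c", 1:5), "hub", "noise1", "noise2",
             sprintf("bg%02d", 1:92))
  sub <- direct_interaction_subgraph(toy_net(e, genes = genes),
                                     paste0("c", 1:5))
  curve <- degree_sweep(sub, k_max = 5, N = 100)
  # pruning noise partners sharpens the enrichment
  expect_lt(curve$p[2], curve$p[1])
  expect_true(all(diff(curve$n_genes) <= 0))
  # k_max = 1 equals the unpruned subgraph statistics
  k1 <- degree_sweep(sub, k_max = 1, N = 100)
  expect_identical(k1$n_genes, length(network_genes(sub)))
  expect_equal(k1$p, enrichment_fisher(network_genes(sub), paste0("c", 1:5),
                                       100))
  # empty candidate set -> single row with p = 1
  sub0 <- direct_interaction_subgraph(toy_net(e, genes = genes),
                                      character())
  curve0 <- degree_sweep(sub0, k_max = 3, N = 100)
  expect_identical(curve0$n_genes, 0L)
  expect_identical(curve0$p, 1)
})

test_that("permutation null flags the planted module and tolerates n_perm = 1", {
  fx <- planted_network_fixture()
  f <- filter_by_probability(fx$net, 0.90)
  sub <- direct_interaction_subgraph(f, fx$module)
  obs <- degree_sweep(sub, k_max = 4)
  null <- permutation_null(f, n = length(fx$module), k_max = 4,
                           n_perm = 100, seed = 5)
  expect_lt(min(obs$p), null$summary$p_q05[1])
  expect_lt(min(obs$p), min(null$minima))
  one <- permutation_null(f, n = 5, k_max = 3, n_perm = 1, seed = 2)
  expect_identical(dim(one$p), c(1L, 3L))
  expect_identical(nrow(one$summary), 3L)
})

test_that("random candidate sets stay inside their own permutation envelope", {
  fx <- planted_network_fixture(p_background = 0.0, seed = 11)
  # make a universe where *some* random structure survives the filter
  genes <- fx$genes
  withr::with_seed(40, {
    e <- data.frame(gene_a = sample(genes, 300, TRUE),
                    gene_b = sample(genes, 300, TRUE),
                    probability = runif(300, 0.9, 1))
    e <- e[e$gene_a != e$gene_b, ]
    e <- e[!duplicated(paste(pmin(e$gene_a, e$gene_b),
                             pmax(e$gene_a, e$gene_b))), ]
    net <- interactome(e, genes = genes)
    null <- permutation_null(net, n = 12, k_max = 3, n_perm = 60, seed = 7)
    inside <- vapply(1:20, function(i) {
      draw <- sample(genes, 12)
      obs <- degree_sweep(direct_interaction_subgraph(net, draw), k_max = 3)
      all(obs$p >= null$summary$p_q05[obs$k] | obs$p >= 0.05)
    }, TRUE)
    expect_gte(mean(inside), 0.9)
  })
})

test_that("largest component matches a brute-force flood fill", {
  e <- data.frame(
    gene_a = c("a", "b", "c", "x", "y"),
    gene_b = c("b", "c", "d", "y", "z"),
    probability = 0.95)
  net <- toy_net(e)   # components {a,b,c,d} and {x,y,z}
  big <- largest_component(net)
  expect_setequal(network_genes(big), c("a", "b", "c", "d"))
  # connected graph: identity
  expect_identical(largest_component(big)$edges, big$edges)
  # empty network: empty result
  empty <- direct_interaction_subgraph(net, "absent")
  expect_identical(nrow(largest_component(empty)$edges), 0L)
  # oracle: flood fill over adjacency on a random graph
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(8:20, 1)
      v <- sprintf("v%02d", 1:n)
      ee <- data.frame(gene_a = sample(v, 2 * n, TRUE),
                       gene_b = sample(v, 2 * n, TRUE),
                       probability = 0.95)
      ee <- ee[ee$gene_a != ee$gene_b, ]
      ee <- ee[!duplicated(paste(pmin(ee$gene_a, ee$gene_b),
                                 pmax(ee$gene_a, ee$gene_b))), ]
      if (!nrow(ee)) next
      # flood fill
      nodes <- unique(c(ee$gene_a, ee$gene_b))
      comp <- setNames(seq_along(nodes), nodes)
      repeat {
        new <- comp
        for (j in seq_len(nrow(ee))) {
          m <- min(new[ee$gene_a[j]], new[ee$gene_b[j]])
          new[ee$gene_a[j]] <- m
          new[ee$gene_b[j]] <- m
        }
        if (identical(new, comp)) break
        comp <- new
      }
      sizes <- table(comp)
      best_nodes <- names(comp)[comp %in%
                                  names(sizes)[sizes == max(sizes)]]
      got <- network_genes(largest_component(toy_net(ee)))
      expect_true(all(got %in% best_nodes))
      expect_identical(length(got), as.integer(max(sizes)))
    }
  })
})

test_that("degree and radiality match hand computations", {
  # path a-b-c: diameter 2; radiality(b) = 2, radiality(a) = 1.5
  path <- toy_net(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                             probability = 0.95))
  ti <- topology_indices(path)
  expect_equal(ti$radiality[ti$gene == "b"], 2)
  expect_equal(ti$radiality[ti$gene == "a"], 1.5)
  expect_equal(ti$radiality[ti$gene == "c"], 1.5)
  # complete graph K5: radiality 1 everywhere, degree n - 1
  pairs <- t(combn(letters[1:5], 2))
  k5 <- toy_net(data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                           probability = 0.95))
  tk <- topology_indices(k5)
  expect_equal(tk$radiality, rep(1, 5))
  expect_identical(tk$degree, rep(4L, 5))
  # star: center degree 5
  star <- toy_net(data.frame(gene_a = "hub", gene_b = paste0("l", 1:5),
                             probability = 0.95))
  ts <- topology_indices(star)
  expect_identical(ts$degree[ts$gene == "hub"], 5L)
})

test_that("graph operations ignore edge-file row order", {
  fx <- planted_network_fixture(n_genes = 60, module_size = 8, seed = 19)
  e <- fx$net$edges
  withr::with_seed(4, perm <- sample(nrow(e)))
  net2 <- interactome(e[perm, ], genes = fx$net$genes)
  expect_identical(fx$net$edges, net2$edges)
  sub1 <- direct_interaction_subgraph(filter_by_probability(fx$net),
                                      fx$module)
  sub2 <- direct_interaction_subgraph(filter_by_probability(net2),
                                      fx$module)
  expect_identical(degree_sweep(sub1, k_max = 3),
                   degree_sweep(sub2, k_max = 3))
  expect_identical(topology_indices(sub1), topology_indices(sub2))
})
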