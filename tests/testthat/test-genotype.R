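test_that("gene domains build connected neighbourhoods over all values", {
  dom <- gene_domains()
  expect_named(dom$genes, gene_names(), ignore.order = TRUE)
  for (g in gene_names()) {
    gd <- dom$genes[[g]]
    # every value has at least one neighbour and distances are finite
    expect_true(all(lengths(gd$adjacency) >= 1))
    for (v in seq_along(gd$values))
      expect_true(length(gd$shortest_paths[[1]][[v]]) >= 1)
  }
  expect_error(gene_domains(electrodes = c("Fp1", "O2"),
                            electrode_graph = matrix(character(0), ncol = 2)),
               "connected")
})

test_that("random individuals are uniform over gene domains", {
  dom <- gene_domains()
  set.seed(5)
  inds <- replicate(1000, random_individual(dom), simplify = FALSE)
  for (ind in inds[1:20]) {
    for (h in ind$hyper_features)
      for (g in gene_names())
        expect_true(h[[g]] %in% dom$genes[[g]]$values)
  }
  # 5000 electrode draws against the uniform distribution
  elec <- unlist(lapply(inds, function(i)
    vapply(i$hyper_features, `[[`, character(1), "electrode")))
  chi <- suppressWarnings(chisq.test(table(factor(elec,
                                                  levels = montage_1020()))))
  expect_gt(chi$p.value, 1e-3)
  # fixed seed reproduces the draw
  set.seed(99)
  a <- random_individual(dom)
  set.seed(99)
  b <- random_individual(dom)
  expect_identical(a, b)
})

test_that("decoding places the pre-ictal boundary from the slowest instant", {
  dom <- gene_domains()
  set.seed(1)
  ind <- random_individual(dom)
  for (i in 1:5)
    ind$hyper_features[[i]]$time_instant <-
      as.character(c(0, 5, 15, 2, 0)[i])
  ph <- decode_individual(ind, min_preictal = 40)
  expect_equal(ph$pre_ictal_min, 55)
  expect_equal(ph$sop_min, 45)
  expect_equal(ph$sph_min, 10)

  for (i in 1:5) ind$hyper_features[[i]]$time_instant <- "0"
  ph0 <- decode_individual(ind, 40)
  expect_equal(ph0$pre_ictal_min, 40)
  expect_equal(ph0$sop_min, 30)

  # dominance: the non-expressed feature gene is phenotypically silent
  ind$hyper_features[[1]]$dominant_feature <- "band_wave"
  ph_a <- decode_individual(ind, 40)
  ind$hyper_features[[1]]$non_band_wave_feature <- "amplitude_variance"
  ph_b <- decode_individual(ind, 40)
  expect_identical(ph_a$recipes, ph_b$recipes)
})

test_that("mutation is a single unitary neighbourhood step", {
  dom <- gene_domains()
  set.seed(8)
  base <- random_individual(dom)
  picks <- integer(5)
  for (rep in 1:400) {
    mut <- mutate_individual(base, dom)
    expect_identical(genotype_distance(base, mut), 1L)
    # locate the mutated gene and check neighbourhood membership
    for (i in 1:5) for (g in gene_names()) {
      old <- base$hyper_features[[i]][[g]]
      new <- mut$hyper_features[[i]][[g]]
      if (!identical(old, new)) {
        gd <- dom$genes[[g]]
        nb <- gd$values[gd$adjacency[[match(old, gd$values)]]]
        expect_true(new %in% nb)
        picks[i] <- picks[i] + 1L
      }
    }
  }
  # each hyper-feature selected roughly 20% of the time
  expect_true(all(abs(picks / 400 - 0.2) < 3 * sqrt(0.2 * 0.8 / 400)
                  + 0.02))
})

test_that("recombination draws genes from shortest paths between parents", {
  dom <- gene_domains()
  set.seed(12)
  p <- random_individual(dom)
  expect_identical(genotype_distance(recombine_individuals(p, p, dom), p),
                   0L)

  # ordinal chain: parents at instants 3 and 7 bound the offspring
  a <- p; b <- p
  for (i in 1:5) {
    a$hyper_features[[i]]$time_instant <- "3"
    b$hyper_features[[i]]$time_instant <- "7"
  }
  for (rep in 1:50) {
    off <- recombine_individuals(a, b, dom)
    ti <- as.integer(vapply(off$hyper_features, `[[`, character(1),
                            "time_instant"))
    expect_true(all(ti >= 3 & ti <= 7))
    for (h in off$hyper_features)
      for (g in gene_names())
        expect_true(h[[g]] %in% dom$genes[[g]]$values)
  }
})

test_that("shortest-path choice matches the BFS oracle", {
  dom <- gene_domains()
  adj <- gene_adjacency(dom, "electrode")
  vals <- dom$genes$electrode$values
  set.seed(30)
  for (pair in list(c("Fp1", "O2"), c("T3", "T4"), c("F7", "F7"))) {
    u <- pair[1]; v <- pair[2]
    oracle <- sort(vals[bfs_shortest_path_nodes(adj, match(u, vals),
                                                match(v, vals))])
    draws <- replicate(600, shortest_path_choice(dom, "electrode", u, v))
    expect_true(all(draws %in% oracle))
    if (u == v) expect_identical(unique(draws), u)
    else expect_setequal(unique(draws), oracle)
  }

  # chain a-b-c: each node with probability ~ 1/3
  chain <- gene_domains(electrodes = c("Fp1", "F3", "C3"),
                        electrode_graph = rbind(c("Fp1", "F3"),
                                                c("F3", "C3")))
  draws <- replicate(3000, shortest_path_choice(chain, "electrode",
                                                "Fp1", "C3"))
  freq <- table(draws) / 3000
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 3000)))

  # complete graph: only the endpoints lie on shortest paths
  labs <- c("Fp1", "Fp2", "F3", "F4")
  complete <- t(combn(labs, 2))
  comp <- gene_domains(electrodes = labs, electrode_graph = complete)
  draws <- replicate(400, shortest_path_choice(comp, "electrode",
                                               "Fp1", "F4"))
  expect_setequal(unique(draws), c("Fp1", "F4"))
})

test_that("individuals serialize to JSON and back", {
  dom <- gene_domains()
  set.seed(2)
  ind <- random_individual(dom)
  ind$fitness <- 0.5
  back <- individual_from_json(individual_to_json(ind))
  expect_identical(genotype_distance(ind, back), 0L)
  expect_equal(back$fitness, 0.5)
})
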