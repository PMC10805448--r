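test_that("distance matrices match hop counts and 1/w lengths", {
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 1
  chain[2, 3] <- chain[3, 2] <- 1
  d <- distance_matrix(as_conn(chain, "FA_bin"))
  expect_equal(d[1, 3], 2)
  expect_identical(attr(d, "mode"), "binary")

  single <- matrix(0, 3, 3)
  single[1, 2] <- single[2, 1] <- 0.5
  dw <- distance_matrix(as_conn(single, "FA_wei"))
  expect_equal(dw[1, 2], 2)          # length = 1/0.5
  expect_true(is.infinite(dw[1, 3])) # unreachable sentinel
  expect_equal(attr(dw, "n_unreachable_pairs"), 4L)

  neg <- single; neg[1, 2] <- -0.5
  expect_error(distance_matrix(as_conn(neg, "FA_wei")), "negative")
})

test_that("complete-graph and star identities hold exactly", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  gm <- global_metrics(as_conn(k4, "FA_bin"))
  expect_equal(gm$Eg, 1)
  expect_equal(gm$Cp, 1)
  expect_equal(gm$Eloc, 1)
  expect_equal(gm$Lp, 1)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  gs <- global_metrics(as_conn(star, "FA_bin"))
  expect_equal(gs$Eg, 0.75)  # 6 ordered pairs at d=1, 6 at d=2
  expect_equal(gs$Cp, 0)

  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 0.5
  tri <- tri + t(tri)
  gt <- global_metrics(as_conn(tri, "FA_wei"))
  expect_equal(gt$Eg, 0.5)   # all lengths 1/0.5 = 2
  expect_equal(gt$Lp, 2)
})

test_that("nodal efficiency matches hand enumeration and aggregates to Eg", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  nm <- nodal_metrics(as_conn(k4, "FA_bin"))
  expect_equal(nm$Enodal, rep(1, 4))
  expect_equal(nm$degree, rep(3L, 4))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  np <- nodal_metrics(as_conn(path, "FA_bin"))
  expect_equal(np$Enodal, c(0.75, 1, 0.75))  # (1 + 1/2)/2 at the ends
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(404)
  n_cases <- 120L
  for (case in seq_len(n_cases)) {
    n <- sample(4:12, 1)
    binary <- case %% 2 == 0
    w <- random_test_graph(n, p_edge = runif(1, 0.2, 0.8), binary = binary)
    kind <- if (binary) "FA_bin" else "FA_wei"
    mat <- as_conn(w, kind)
    d <- distance_matrix(mat)
    o <- oracle_metrics(w, binary)
    expect_equal(matrix(as.numeric(d), n, n), o$d, tolerance = 1e-9)
    gm <- global_metrics(mat, d)
    nm <- nodal_metrics(mat, d)
    expect_equal(gm$Eg, o$Eg, tolerance = 1e-9)
    expect_equal(gm$Lp, o$Lp, tolerance = 1e-9)
    expect_equal(nm$Enodal, o$Enodal, tolerance = 1e-9)
    expect_equal(nm$degree, as.integer(o$degree))
    ci <- if (binary) oracle_clustering_binary(w) else
      oracle_clustering_onnela(w)
    expect_equal(gm$Cp, mean(ci), tolerance = 1e-9)
    # exact identity: mean nodal efficiency is global efficiency
    expect_equal(mean(nm$Enodal), gm$Eg, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabelling", {
  set.seed(17)
  for (rep in 1:10) {
    w <- random_test_graph(9, 0.5, binary = rep %% 2 == 0)
    kind <- if (rep %% 2 == 0) "FA_bin" else "FA_wei"
    perm <- sample(9)
    wp <- w[perm, perm]
    a <- global_metrics(as_conn(w, kind))
    b <- global_metrics(as_conn(wp, kind))
    expect_equal(a$Eg, b$Eg, tolerance = 1e-12)
    expect_equal(a$Cp, b$Cp, tolerance = 1e-12)
    expect_equal(a$Eloc, b$Eloc, tolerance = 1e-12)
    expect_equal(a$Lp, b$Lp, tolerance = 1e-12)
    na <- nodal_metrics(as_conn(w, kind))
    nb <- nodal_metrics(as_conn(wp, kind))
    expect_equal(na$Enodal[perm], nb$Enodal, tolerance = 1e-12)
  }
})

test_that("deleting an edge never increases efficiency or shortens paths", {
  set.seed(23)
  for (rep in 1:10) {
    w <- random_test_graph(10, 0.5, binary = FALSE)
    edges <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    if (!nrow(edges)) next
    pick <- edges[sample(nrow(edges), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- 0
    d1 <- distance_matrix(as_conn(w, "FA_wei"))
    d2 <- distance_matrix(as_conn(w2, "FA_wei"))
    expect_true(all(unclass(d2) >= unclass(d1) - 1e-12))
    expect_lte(global_metrics(as_conn(w2, "FA_wei"), d2)$Eg,
               global_metrics(as_conn(w, "FA_wei"), d1)$Eg + 1e-12)
  }
})

test_that("hub detection flags exceptional group-mean degree", {
  flat <- data.frame(subject_id = rep(c("a", "b"), each = 5),
                     region = rep(1:5, 2), degree = 4)
  ht <- hub_detection(flat, atlas = aal_atlas())
  expect_false(any(ht$hub))  # zero spread, no hubs

  spiked <- flat
  spiked$degree[spiked$region == 3] <- 40
  ht2 <- hub_detection(spiked, atlas = aal_atlas())
  expect_identical(ht2$region[ht2$hub], 3L)
  expect_equal(attr(ht2, "threshold"),
               attr(ht2, "grand_mean") + attr(ht2, "sd"))

  expect_error(hub_detection(flat[flat$subject_id == "a", ]), "2 subjects")
})

test_that("hub sets are stable across independent cohorts", {
  hubset <- function(seed) {
    sim <- simulate_cohort(cohort_params(), seed = seed)
    ids <- sim$subjects$subject_id[sim$subjects$group == "control"]
    deg <- do.call(rbind, lapply(ids, function(id) {
      nets <- build_networks(sim$streamlines[[id]], subject_id = id)
      nm <- nodal_metrics(nets$FA_bin)
      data.frame(subject_id = id, region = nm$region, degree = nm$degree)
    }))
    ht <- hub_detection(deg)
    ht$region[ht$hub]
  }
  sets <- lapply(1:5, hubset)
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  pairwise <- sapply(1:4, function(i) jaccard(sets[[i]], sets[[i + 1]]))
  expect_gte(mean(pairwise), 0.8)
  # hubs concentrate on the planted high-degree backbone
  backbone <- cohort_params()$hub_regions
  expect_gte(mean(unlist(sets) %in% backbone), 0.8)
})
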