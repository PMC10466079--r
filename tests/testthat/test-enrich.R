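toy_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

test_that("GMT parsing reads sets, dedupes members, and validates lines", {
  gsc <- read_gmt(toy_gmt(c("setA\tfirst set\tg1\tg2\tg3",
                            "setB\tsecond\tg2\tg4\tg4")))
  expect_named(gsc, c("setA", "setB"))
  expect_identical(gsc$setA$members, c("g1", "g2", "g3"))
  expect_length(gsc$setB$members, 2L)  # repeated member counted once
  expect_error(read_gmt(toy_gmt("lonely\tdescription")), "fewer than 3")
})

test_that("GMT collections round-trip through write and read", {
  set.seed(77)
  genes <- sprintf("G%03d", 1:300)
  sets <- lapply(1:100, function(i)
    list(description = paste("set", i),
         members = sample(genes, sample(5:30, 1))))
  names(sets) <- sprintf("S%03d", 1:100)
  gsc <- structure(sets, class = "GeneSetCollection")
  path <- tempfile(fileext = ".gmt")
  write_gmt(gsc, path)
  back <- read_gmt(path)
  expect_equal(unclass(back), unclass(gsc))
})

test_that("ORA reproduces the exact hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  gsc <- structure(list(hit5 = list(description = "", members = universe[1:5])),
                   class = "GeneSetCollection")
  query <- c(universe[1:3], universe[11:12])  # k = 3 of K = 5, n = 5
  res <- ora_hypergeometric(query, universe, gsc, min_size = 1)
  expect_equal(res$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 3L, K = 5L, n = 5L, N = 20L),
               ignore_attr = TRUE)
  # k = 0 tail is certain
  query0 <- universe[11:15]
  expect_equal(ora_hypergeometric(query0, universe, gsc, min_size = 1)$p, 1)
  # query = universe makes every overlap certain
  resU <- ora_hypergeometric(universe, universe, gsc, min_size = 1)
  expect_equal(resU$k, resU$K)
  expect_equal(resU$p, 1)
})

test_that("ORA matches exhaustive enumeration on random small instances", {
  set.seed(31)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    universe <- sprintf("u%02d", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    gsc <- structure(list(s = list(description = "",
                                   members = sample(universe, K))),
                     class = "GeneSetCollection")
    query <- sample(universe, n)
    res <- ora_hypergeometric(query, universe, gsc, min_size = 1,
                              max_size = N)
    k <- length(intersect(query, gsc$s$members))
    expect_equal(res$p, hyper_tail_enum(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("ORA validates query/universe relations", {
  universe <- sprintf("g%d", 1:30)
  gsc <- structure(list(s = list(description = "", members = universe[1:10])),
                   class = "GeneSetCollection")
  expect_warning(ora_hypergeometric(c(universe[1:3], "alien"), universe, gsc,
                                    min_size = 1), "outside the universe")
  expect_error(suppressWarnings(
    ora_hypergeometric("alien", universe, gsc, min_size = 1)), "empty query")
})

test_that("GSEA attains +/-1 for perfectly concentrated sets at exponent 0", {
  scores <- setNames(seq(10, 1), paste0("g", 1:10))
  top <- structure(list(s = list(description = "", members = paste0("g", 1:3))),
                   class = "GeneSetCollection")
  bottom <- structure(list(s = list(description = "",
                                    members = paste0("g", 8:10))),
                      class = "GeneSetCollection")
  expect_equal(gsea(scores, top, weight_exponent = 0, n_perm = 50,
                    seed = 1, min_size = 1)$es, 1)
  expect_equal(gsea(scores, bottom, weight_exponent = 0, n_perm = 50,
                    seed = 1, min_size = 1)$es, -1)
  # ES at exponent 0 is invariant to positive rescaling of the scores
  gsc <- structure(list(s = list(description = "",
                                 members = paste0("g", c(2, 5, 9)))),
                   class = "GeneSetCollection")
  e1 <- gsea(scores, gsc, weight_exponent = 0, n_perm = 10, seed = 1,
             min_size = 1)$es
  e2 <- gsea(scores * 37.5, gsc, weight_exponent = 0, n_perm = 10, seed = 1,
             min_size = 1)$es
  expect_identical(e1, e2)
})

test_that("GSEA running sum matches the brute-force oracle", {
  scores <- setNames(c(5, 4, 3.5, 3, 2.5, 2, 1.5, 1, 0.5, 0.25),
                     paste0("g", 1:10))
  gsc <- structure(list(s = list(description = "",
                                 members = paste0("g", c(1, 4, 8)))),
                   class = "GeneSetCollection")
  res <- gsea(scores, gsc, weight_exponent = 1, n_perm = 100, seed = 3,
              min_size = 1)
  expect_equal(res$es, es_bruteforce(c(1, 4, 8), scores, 1),
               tolerance = 1e-12)
  # random instances, mixed-sign scores
  set.seed(91)
  for (i in 1:15) {
    N <- sample(15:60, 1)
    sc <- sort(rnorm(N), decreasing = TRUE)
    names(sc) <- paste0("x", seq_len(N))
    pos <- sort(sample(N, sample(3:8, 1)))
    g <- structure(list(s = list(description = "", members = names(sc)[pos])),
                   class = "GeneSetCollection")
    r <- gsea(sc, g, weight_exponent = 1, n_perm = 10, seed = i,
              min_size = 1)
    expect_equal(r$es, es_bruteforce(pos, sc, 1), tolerance = 1e-12)
  }
})

test_that("GSEA permutation p agrees with a long-run permutation oracle", {
  scores <- setNames(c(4, 3, 2.5, 2, 1.8, 1.5, 1.2, 1, 0.8, 0.5),
                     paste0("g", 1:10))
  pos <- c(1, 4, 8)
  gsc <- structure(list(s = list(description = "",
                                 members = paste0("g", pos))),
                   class = "GeneSetCollection")
  res <- gsea(scores, gsc, weight_exponent = 1, n_perm = 2000, seed = 11,
              min_size = 1)
  set.seed(99)
  es_obs <- es_bruteforce(pos, scores, 1)
  perm <- replicate(100000,
                    es_bruteforce(sort(sample.int(10, 3)), scores, 1))
  same <- perm[sign(perm) == sign(es_obs)]
  oracle_p <- mean(abs(same) >= abs(es_obs))
  # binomial error of the 2000-permutation estimate
  se <- sqrt(oracle_p * (1 - oracle_p) / 2000)
  expect_lt(abs(res$perm_p - oracle_p), 4 * se + 0.01)
})
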