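# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# all C(N, n) draws of the query from the universe, exact rational count.
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K universe elements are the signature
  mean(hits >= k)
}

test_that("hypergeometric overlap matches exhaustive enumeration", {
  # frozen case: N=10, K=4, n=5, k>=3 -> 66/252
  res <- hypergeometric_overlap(
    query = c("a", "b", "c", "d", "e"),
    signature = c("a", "b", "c", "z"), universe = 10)
  expect_equal(res$n_overlap, 3)
  expect_equal(res$p_hypergeometric, 66 / 252, tolerance = 1e-12)
  expect_equal(enum_hyper_p(10, 4, 5, 3), 66 / 252)

  for (case in list(c(8, 3, 4, 2), c(12, 5, 6, 3), c(9, 4, 4, 0),
                    c(11, 6, 5, 5))) {
    N <- case[1]; K <- case[2]; n <- case[3]; k <- case[4]
    expect_equal(
      phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      enum_hyper_p(N, K, n, k), tolerance = 1e-12,
      label = paste("N,K,n,k =", paste(case, collapse = ",")))
  }

  # degenerate certainty and zero overlap
  expect_equal(hypergeometric_overlap(letters[1:4], letters[1:4],
                                      4)$p_hypergeometric, 1)
  expect_equal(hypergeometric_overlap(letters[1:3], letters[10:12],
                                      20)$p_hypergeometric, 1)
  expect_error(hypergeometric_overlap(letters[1:5], letters[1:4], 4),
               "universe")

  # p monotone nonincreasing in the overlap at fixed margins
  p_at <- function(k) phyper(k - 1, 6, 14, 8, lower.tail = FALSE)
  expect_true(all(diff(p_at(0:6)) <= 0))
})

test_that("ortholog mapping is audited, never silent", {
  map <- data.frame(from = c("a", "b", "c"), to = c("A", "B", "C"))
  res <- map_orthologs(c("a", "b", "q"), map)
  expect_equal(unname(res$mapped), c("A", "B"))
  expect_equal(res$unmapped, "q")
  expect_equal(map_orthologs(character(), map)$mapped,
               setNames(character(), character()))

  # identity map round-trips
  idm <- data.frame(from = letters[1:5], to = letters[1:5])
  expect_equal(unname(map_orthologs(letters[1:5], idm)$mapped), letters[1:5])

  # 70 queried, 49 covered -> 49 mapped, 21 unmapped
  big <- data.frame(from = sprintf("pig%02d", 1:49),
                    to = sprintf("HUM%02d", 1:49))
  res70 <- map_orthologs(sprintf("pig%02d", 1:70), big)
  expect_length(res70$mapped, 49)
  expect_length(res70$unmapped, 21)

  amb <- rbind(map, data.frame(from = "a", to = "A2"))
  expect_error(map_orthologs("a", amb), "one-to-many")
  expect_equal(unname(map_orthologs("a", amb, tie_break = "first")$mapped),
               "A")
})

test_that("concordance labels follow the protective-arm polarity", {
  de <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                   direction = c("NEVKP", "NEVKP", "SCS", "SCS", "NEVKP"),
                   stringsAsFactors = FALSE)
  sig <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    direction = c("down_in_injury", "up_in_injury",
                                  "up_in_injury", "down_in_injury"),
                    stringsAsFactors = FALSE)
  lab <- classify_concordance(de, sig)
  expect_equal(lab$label,
               c("opposing",    # NEVKP-increased, injury-decreased
                 "concordant",  # NEVKP-increased, injury-increased
                 "opposing",    # SCS-increased, injury-increased
                 "concordant",  # SCS-increased, injury-decreased
                 "undirected")) # absent from signature

  # flipping polarity swaps opposing <-> concordant exactly
  lab2 <- classify_concordance(de, sig, polarity = "SCS")
  swap <- c(opposing = "concordant", concordant = "opposing",
            undirected = "undirected")
  expect_equal(lab2$label, unname(swap[lab$label]))

  ov <- signature_overlap(de, sig, universe = 100)
  expect_equal(ov$n_overlap, 4)
  expect_equal(ov$n_opposing + ov$n_concordant, 4)
  expect_equal(ov$n_opposing, 2)
})

test_that("ORA ranks sets and reports gene ratios", {
  q <- sprintf("g%02d", 1:10)
  coll <- list(self = q,
               half = q[1:5],
               other = sprintf("x%02d", 1:8))
  res <- ora(q, coll, universe = 500)
  expect_equal(res$set[1], "self")
  expect_equal(res$gene_ratio[res$set == "half"], 0.5)
  expect_equal(res$p[res$set == "other"], 1)
  expect_equal(res$q, bh_adjust(res$p)[order(order(res$p))],
               ignore_attr = TRUE)
  expect_equal(nrow(ora(q, list(), 500)), 0)

  # small-N enumeration oracle for the fully-contained set
  p_self <- phyper(9, 10, 490, 10, lower.tail = FALSE)
  expect_equal(res$p[res$set == "self"], p_self)
  expect_equal(p_self, 1 / choose(500, 10) * choose(490, 0), tolerance = 1e-12)

  # GMT round trip
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdescA\tg01\tg02\tg03",
               "setB\tdescB\tx01\tx02"), path)
  gmt <- read_gmt(path)
  expect_equal(names(gmt), c("setA", "setB"))
  expect_equal(gmt$setA, c("g01", "g02", "g03"))
})
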