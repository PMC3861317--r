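# Gene ranking, sequential Fisher scan and BH FDR.

test_that("gene ranking takes the per-gene minimum with deterministic ties", {
  res <- data.frame(gene = c("G2", "G2", "G1", "G3"),
                    p = c(0.04, 0.20, 0.04, 0.01),
                    model = "rg1", phenotype_id = "PH")
  r <- rankGenes(res)
  expect_identical(r$gene, c("G3", "G1", "G2"))  # ties broken by gene id
  expect_equal(r$p, c(0.01, 0.04, 0.04))

  expect_error(rankGenes(res[0, ]), "empty")
  resMix <- rbind(res, data.frame(gene = "G4", p = 0.5, model = "additive",
                                  phenotype_id = "PH"))
  expect_error(rankGenes(resMix), "single model")
})

test_that("pooled ranking keeps each gene once at its best phenotype p", {
  res <- data.frame(gene = c("G1", "G1", "G2", "G2"),
                    p = c(0.01, 0.8, 0.3, 0.2),
                    model = "rg1",
                    phenotype_id = c("CA", "SKN", "HEM", "MET"))
  r <- rankGenes(res, mode = "pooled")
  expect_identical(nrow(r), 2L)
  expect_identical(r$source[r$gene == "G1"], "CA")
  expect_identical(r$source[r$gene == "G2"], "MET")
})

test_that("ranking matches a brute-force sort oracle", {
  withr::local_seed(61)
  res <- data.frame(gene = sample(sprintf("G%02d", 1:40), 200, replace = TRUE),
                    p = round(runif(200), 2), model = "rg1",
                    phenotype_id = "PH")
  r <- rankGenes(res)
  oracle <- aggregate(p ~ gene, res, min)
  oracle <- oracle[order(oracle$p, oracle$gene), ]
  expect_identical(r$gene, oracle$gene)
  expect_equal(r$p, oracle$p)
})

test_that("ontology Fisher p matches brute-force hypergeometric sums", {
  # top-2 of 748 genes, both annotated, 2 annotated in the universe
  expect_equal(ontologyFisher(k = 2, a = 2, N = 748, K = 2),
               1 / choose(748, 2), tolerance = 1e-12)
  expect_identical(ontologyFisher(k = 10, a = 0, N = 100, K = 5), 1)
  expect_error(ontologyFisher(k = 5, a = 6, N = 10, K = 6), "impossible")

  withr::local_seed(67)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    K <- sample(0:N, 1)
    k <- sample(1:N, 1)
    a <- sample(0:min(k, K), 1)
    expect_equal(ontologyFisher(k, a, N, K), oracleHyperTail(a, K, N, k),
                 tolerance = 1e-12, info = sprintf("N=%d K=%d k=%d a=%d", N, K, k, a))
  }
})

test_that("sequential scan: toy geometry, saturation, tie blocks", {
  # 6-gene universe; term carried only by the two top-ranked genes
  ranked <- data.frame(gene = sprintf("G%d", 1:6),
                       p = c(0.001, 0.002, 0.01, 0.02, 0.03, 0.04),
                       source = "PH")
  # GO:all annotates every gene, so its scan p is 1 at every k
  ann <- OntologyAnnotation(list(G1 = c("GO:top", "GO:all"),
                                 G2 = c("GO:top", "GO:all"),
                                 G3 = "GO:all", G4 = "GO:all",
                                 G5 = "GO:all", G6 = "GO:all"),
                            c("GO:top" = "top pair", "GO:all" = "everything"))
  res <- sequentialScan(ranked, ann, pCut = 0.05)
  top <- res[res$ontology_id == "GO:top", ]
  expect_identical(top$k_selected, 2L)
  expect_equal(top$fisher_p, 1 / choose(6, 2), tolerance = 1e-12)
  expect_equal(top$p_threshold, 0.002)
  expect_identical(top$genes, "G1,G2")
  allTerm <- res[res$ontology_id == "GO:all", ]
  expect_identical(allTerm$fisher_p, 1)

  # tied p at the boundary: both tied genes enter together
  rankedTie <- ranked
  rankedTie$p <- c(0.001, 0.002, 0.002, 0.02, 0.03, 0.04)
  resTie <- sequentialScan(rankedTie, ann, pCut = 0.05)
  expect_false(2L %in% resTie$k_selected)  # k jumps 1 -> 3 over the tie

  # no genes under the cut-off -> empty result with message
  expect_message(resEmpty <- sequentialScan(ranked, ann, pCut = 1e-6), "skipped")
  expect_identical(nrow(resEmpty), 0L)
})

test_that("scan reports the seeded top-k geometry on a thrombosis-like fixture", {
  # 404-gene universe; a coagulation term annotates 3 genes seeded into the
  # top 8 ranks; optimum must be at k = 8 with all 3 annotated genes
  withr::local_seed(71)
  genes <- sprintf("G%03d", 1:404)
  p <- sort(round(runif(404, 0.001, 1), 4))
  p[1:8] <- c(0.001, 0.002, 0.004, 0.005, 0.007, 0.009, 0.011, 0.012)
  p[9] <- 0.06  # only the top 8 sit below the 0.05 cut-off
  ranked <- data.frame(gene = genes, p = p, source = "THROMBOSIS")
  coag <- genes[c(2, 5, 8)]
  sets <- setNames(rep(list(character()), 404), genes)
  for (g in coag) sets[[g]] <- "GO:coag"
  other <- base::sample(genes[9:404], 120)
  for (g in other) sets[[g]] <- c(sets[[g]], "GO:misc")
  ann <- OntologyAnnotation(sets, c("GO:coag" = "blood coagulation"))
  res <- sequentialScan(ranked, ann, pCut = 0.05)
  row <- res[res$ontology_id == "GO:coag", ]
  expect_identical(row$k_selected, 8L)
  expect_identical(row$a_annotated, 3L)
  expect_equal(row$p_threshold, 0.012)
  expect_setequal(strsplit(row$genes, ",")[[1]], coag)
  expect_equal(row$fisher_p, oracleHyperTail(3, 3, 404, 8), tolerance = 1e-12)
})

test_that("scan minimum never rises when annotation moves up the ranking", {
  withr::local_seed(73)
  genes <- sprintf("G%02d", 1:30)
  ranked <- data.frame(gene = genes, p = sort(runif(30, 0, 0.04)), source = "PH")
  sets <- setNames(rep(list(character()), 30), genes)
  annotated <- c(5, 9, 20)
  for (i in annotated) sets[[genes[i]]] <- "GO:x"
  pWorse <- sequentialScan(ranked, OntologyAnnotation(sets), pCut = 0.05)$fisher_p
  # move the deepest annotated gene to the top: min-p can only improve
  sets[[genes[20]]] <- character()
  sets[[genes[1]]] <- "GO:x"
  pBetter <- sequentialScan(ranked, OntologyAnnotation(sets), pCut = 0.05)$fisher_p
  expect_lte(pBetter, pWorse)
})

test_that("BH adjustment matches the step-up oracle and respects the universe size", {
  q <- bhAdjust(c(2e-5, 3e-5, 3e-5), m = 2623)
  expect_equal(round(q[1], 2), 0.03)
  expect_equal(q, oracleBH(c(2e-5, 3e-5, 3e-5), 2623), tolerance = 1e-12)

  expect_equal(bhAdjust(0.04, m = 1), 0.04)
  expect_error(bhAdjust(c(0.1, 0.2), m = 1), "universe")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(79)
  for (i in 1:200) {
    nn <- sample(1:40, 1)
    p <- runif(nn)
    m <- nn + sample(0:2000, 1)
    expect_equal(bhAdjust(p, m), oracleBH(p, m), tolerance = 1e-12)
  }
})

test_that("significance rule needs both FDR < 0.05 and more than one annotated gene", {
  ranked <- data.frame(gene = sprintf("G%d", 1:50),
                       p = c(0.001, 0.002, sort(runif(48, 0.06, 1))),
                       source = "PH")
  sets <- setNames(rep(list(character()), 50), ranked$gene)
  sets$G1 <- "GO:pair"; sets$G2 <- "GO:pair"
  sets$G3 <- "GO:solo"
  res <- sequentialScan(ranked, OntologyAnnotation(sets), pCut = 0.05)
  pair <- res[res$ontology_id == "GO:pair", ]
  expect_true(pair$significant)
  solo <- res[res$ontology_id == "GO:solo", ]
  expect_false(isTRUE(solo$significant))
})
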