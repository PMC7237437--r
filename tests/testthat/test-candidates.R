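test_that("candidate names reproduce the published naming scheme", {
  expect_equal(name_candidate("DrMe", "F", 13450, "r"), "DrMe_F_smithRNA134r")
  expect_equal(name_candidate("DaRe", "F", 1020, "r"), "DaRe_F_smithRNA10r")
  expect_equal(name_candidate("MuMu", "F", 15600, "nc"),
               "MuMu_F_smithRNA156nc")
})

test_that("naming is injective for loci at least 100 bp apart", {
  set.seed(31)
  starts <- sort(sample(seq(100, 15000, by = 100), 30)) + sample(0:99, 30, TRUE)
  starts <- starts[c(TRUE, diff(starts) >= 100)]
  nm <- vapply(starts, function(s) name_candidate("SySp", "F", s, "r"),
               character(1))
  expect_equal(anyDuplicated(nm), 0)
})

test_that("pre-regions are 70 bp centered with ceil/floor flanks", {
  tg <- make_tiny_genome()
  # 22-nt candidate: flanks are ceil(48/2)=24 left, 24 right
  pr <- extract_pre_region(300, 321, "+", tg$annotation, tg$genome)
  expect_equal(c(pr$pre_start, pr$pre_end), c(276, 345))
  expect_equal(nchar(pr$pre_sequence), 70)
  # odd-length candidate: left flank gets the extra base
  pr2 <- extract_pre_region(300, 320, "+", tg$annotation, tg$genome)
  expect_equal(c(pr2$pre_start, pr2$pre_end), c(275, 344))
  expect_error(extract_pre_region(300, 380, "+", tg$annotation, tg$genome),
               "shorter than the candidate")
})

test_that("tRNA candidates take the whole tRNA plus flanking UR nucleotides", {
  set.seed(32)
  g <- circular_genome("mt", random_seq(6000))
  feats <- rbind(genome_feature("cox1", "PCG", 100, 4989),
                 genome_feature("trnX", "tRNA", 5000, 5070),
                 genome_feature("cox2", "PCG", 5081, 5900))
  ann <- reannotate_urs(annotation_set("mt", feats, length = 6000), g)
  # URs are 4990-4999, 5071-5080 and 5901-99 (wrap)
  pr <- extract_pre_region(5020, 5041, "+", ann, g)
  expect_equal(pr$category, "t")
  expect_equal(c(pr$pre_start, pr$pre_end), c(4990, 5080))
})

test_that("pre-regions always contain the mature locus", {
  tg <- make_tiny_genome()
  set.seed(33)
  for (i in 1:20) {
    s <- sample(3000, 1)
    e <- (s + 21 - 1) %% 3000 + 1
    pr <- extract_pre_region(s, e, "+", tg$annotation, tg$genome)
    span <- if (pr$pre_end >= pr$pre_start) pr$pre_start:pr$pre_end
            else c(pr$pre_start:3000, 1:pr$pre_end)
    locus <- if (e >= s) s:e else c(s:3000, 1:e)
    expect_true(all(locus %in% span))
  }
})

test_that("context folding gives balanced non-crossing complementary pairs", {
  expect_equal(fold_context(strrep("A", 40))$structure, strrep(".", 40))
  fc <- fold_context("GGGGAAAACCCC")
  expect_equal(fc$structure, "((((....))))")
  expect_equal(fc$n_pairs, 4)
  m <- energy_model()
  expect_equal(fc$energy, 3 * m$stack["GC", "GC"], tolerance = 1e-12)
  set.seed(34)
  for (i in 1:10) {
    s <- random_seq(sample(40:90, 1))
    fc <- fold_context(s)
    db <- strsplit(fc$structure, "")[[1]]
    expect_equal(length(db), nchar(s))
    # balanced and non-crossing via a stack; pairs must be complementary
    stack <- integer(0)
    sv <- strsplit(s, "")[[1]]
    ok_pairs <- c("AT", "TA", "CG", "GC", "GT", "TG")
    for (p in seq_along(db)) {
      if (db[p] == "(") stack <- c(stack, p)
      if (db[p] == ")") {
        expect_gt(length(stack), 0)
        q <- stack[length(stack)]; stack <- stack[-length(stack)]
        expect_true(paste0(sv[q], sv[p]) %in% ok_pairs)
        expect_gte(p - q - 1, 3)  # hairpin loop size
      }
    }
    expect_equal(length(stack), 0)
  }
})

test_that("assembled candidates are named, categorized, ordered and written", {
  tg <- make_tiny_genome()
  set.seed(35)
  cen_r <- circular_subseq(tg$genome, 400, 421, "+")
  cen_nc <- circular_subseq(tg$genome, 2600, 2621, "-")
  clusters <- data.frame(cluster_id = c("c1", "c2"),
                         centroid = c(cen_r, cen_nc), size = c(300, 280),
                         start = c(400, 2600), end = c(421, 2621),
                         strand = c("+", "-"), multimap = FALSE,
                         frac5 = 1, frac3 = 1, sharp_pass = TRUE)
  clusters$members <- list(NULL, NULL)
  utrs <- c(u1 = paste0(random_seq(120), rc_dna(cen_r), random_seq(120)),
            u2 = paste0(random_seq(120), rc_dna(cen_nc), random_seq(120)))
  hits <- do.call(rbind, lapply(c(cen_r, cen_nc), function(cen)
    cbind(centroid = cen, evaluate_targets(cen, utrs))))
  cands <- assemble_candidates(clusters, hits, tg$annotation, tg$genome,
                               species_tag = "SyCl", sex_tag = "M")
  expect_equal(nrow(cands), 2)
  expect_equal(cands$name, c("SyCl_M_smithRNA4r", "SyCl_M_smithRNA26nc"))
  expect_equal(cands$category, c("r", "nc"))
  # minus-strand naming uses the 5' (higher) coordinate
  expect_equal(cands$start[2], 2600)
  expect_true(all(grepl("U|^[ACG]+$", cands$sequence)))
  expect_false(any(grepl("T", cands$sequence)))

  out <- tempfile()
  paths <- write_candidate_outputs(cands, out, genome = tg$genome)
  expect_true(all(file.exists(paths)))
  back <- read_annotation_gff3(paths[["gff3"]], genome_length = 3000)
  mature <- back$features[back$features$ftype == "smithRNA", ]
  expect_setequal(mature$start, c(400, 2600))
  expect_setequal(mature$end, c(421, 2621))

  # zero candidates still produce valid (empty) outputs
  none <- assemble_candidates(clusters[0, ], hits[0, ], tg$annotation,
                              tg$genome)
  paths0 <- write_candidate_outputs(none, tempfile(), genome = tg$genome)
  expect_true(all(file.exists(paths0)))
})

test_that("name collisions get deterministic letter suffixes", {
  tg <- make_tiny_genome()
  set.seed(36)
  cen1 <- circular_subseq(tg$genome, 410, 431, "+")
  cen2 <- circular_subseq(tg$genome, 440, 461, "+")
  clusters <- data.frame(cluster_id = c("c1", "c2"),
                         centroid = c(cen1, cen2), size = 300,
                         start = c(410, 440), end = c(431, 461),
                         strand = "+", multimap = FALSE, frac5 = 1,
                         frac3 = 1, sharp_pass = TRUE)
  clusters$members <- list(NULL, NULL)
  utrs <- c(u1 = paste0(random_seq(100), rc_dna(cen1), random_seq(100)),
            u2 = paste0(random_seq(100), rc_dna(cen2), random_seq(100)))
  hits <- do.call(rbind, lapply(c(cen1, cen2), function(cen)
    cbind(centroid = cen, evaluate_targets(cen, utrs))))
  cands <- assemble_candidates(clusters, hits, tg$annotation, tg$genome)
  expect_equal(cands$name,
               c("SySp_F_smithRNA4r", "SySp_F_smithRNA4ra"))
})
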