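# Data model, I/O, pair construction, scaffolds, splits, aggregation.

test_that("ProfileMatrix enforces its invariants", {
  v <- rmat(3, 4, seed = 1)
  pm <- toyProfile(v, c("a", "a", "b"))
  expect_s4_class(pm, "ProfileMatrix")
  expect_equal(unname(profileValues(pm)), unname(v))
  expect_equal(unname(compoundIds(pm)), c("a", "a", "b"))
  expect_equal(modality(pm), "CP")
  # TX requires one profile per compound
  expect_error(toyProfile(v, c("a", "a", "b"), modality = "TX",
                          rowIds = c("r1", "r2", "r3")),
               "one row per compound")
  # missing values rejected
  v[2, 2] <- NA
  expect_error(toyProfile(v, c("a", "b", "c")), "missing")
})

test_that("CSV round trip preserves a random matrix", {
  v <- rmat(10, 8, seed = 7)
  pm <- toyProfile(v, rep(sprintf("c%d", 1:5), each = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  writeProfileMatrix(pm, path)
  back <- readProfileMatrix(path, "CP")
  expect_equal(profileValues(back), profileValues(pm), tolerance = 1e-12)
  expect_equal(compoundIds(back), compoundIds(pm))
})

test_that("readProfileMatrix validates structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row_id,compound_id,f1", "r1,a,0.5", "r2,a,0.1"), path)
  expect_error(readProfileMatrix(path, "TX"), "one row per compound")
  writeLines(c("id,f1", "r1,0.5"), path)
  expect_error(readProfileMatrix(path, "CP"), "row_id")
})

test_that("buildPairs yields one pair per CP replicate of shared compounds", {
  # compound A: 3 replicates + TX; B: CP only; C: TX only
  cp <- toyProfile(rmat(4, 3, seed = 2), c("A", "A", "A", "B"))
  tx <- toyProfile(rmat(2, 3, seed = 3), c("A", "C"), modality = "TX")
  expect_message(ps <- buildPairs(cp, tx), "dropped 1 CP")
  expect_equal(length(ps), 3L)
  expect_true(all(pairTable(ps)$compound_id == "A"))
  # no overlap at all
  txD <- toyProfile(rmat(1, 3, seed = 4), "D", modality = "TX")
  expect_error(buildPairs(cp, txD), "no compound")
})

test_that("pair count equals an exhaustive per-replicate enumeration", {
  set.seed(9)
  nrep <- sample(1:4, 12, replace = TRUE)
  cmp <- sprintf("c%02d", 1:12)
  cp <- toyProfile(rmat(sum(nrep), 5, seed = 5), rep(cmp, nrep))
  txCmp <- cmp[1:9]  # three compounds lack TX
  tx <- toyProfile(rmat(9, 5, seed = 6), txCmp, modality = "TX")
  suppressMessages(ps <- buildPairs(cp, tx))
  # brute-force recount over every CP row
  expected <- sum(vapply(rep(cmp, nrep),
                         function(cc) cc %in% txCmp, NA))
  expect_equal(length(ps), expected)
  expect_equal(length(ps), sum(nrep[1:9]))
})

test_that("Murcko scaffold keys match the cheminformatics toolkit", {
  # benzene is its own scaffold; toluene strips to benzene; ethane is
  # acyclic and maps to the reserved sentinel key
  keys <- murckoKey(c("c1ccccc1", "CC", "Cc1ccccc1"))
  expect_equal(keys, c("c1ccccc1", acyclicScaffoldKey(), "c1ccccc1"))
  expect_error(murckoKey(c("c1ccccc1", "not_a_smiles")), "unparsable")
})

test_that("scaffoldSplit hits exact proportions on divisible groups", {
  cmp <- data.frame(compound_id = sprintf("c%03d", 1:100),
                    scaffold_key = rep(sprintf("s%02d", 1:10), each = 10))
  sp <- scaffoldSplit(cmp, ratios = c(0.7, 0.1, 0.2), seed = 4)
  tab <- table(splitAssignment(sp))
  expect_equal(as.vector(tab[c("train", "valid", "test")]), c(70, 10, 20))
})

test_that("scaffoldSplit is a scaffold-disjoint deterministic partition", {
  set.seed(21)
  nG <- 60
  sizes <- 1L + rgeom(nG, 1 / 3)
  cmp <- data.frame(
    compound_id = sprintf("c%04d", seq_len(sum(sizes))),
    scaffold_key = rep(sprintf("s%03d", seq_len(nG)), times = sizes))
  sp1 <- scaffoldSplit(cmp, seed = 11)
  sp2 <- scaffoldSplit(cmp, seed = 11)
  expect_identical(splitAssignment(sp1), splitAssignment(sp2))
  asn <- splitAssignment(sp1)
  # partition: every compound exactly once
  expect_setequal(names(asn), cmp$compound_id)
  # scaffold containment: one label per scaffold key
  perKey <- tapply(asn[cmp$compound_id], cmp$scaffold_key,
                   function(x) length(unique(x)))
  expect_true(all(perKey == 1L))
  # different seed shuffles equal-size groups but keeps a valid partition
  sp3 <- scaffoldSplit(cmp, seed = 12)
  expect_setequal(names(splitAssignment(sp3)), cmp$compound_id)
})

test_that("a single scaffold degenerates to train with a warning", {
  cmp <- data.frame(compound_id = c("a", "b", "c"),
                    scaffold_key = "only")
  expect_warning(sp <- scaffoldSplit(cmp), "single scaffold")
  expect_true(all(splitAssignment(sp) == "train"))
})

test_that("replicate aggregation matches a sort-based median oracle", {
  set.seed(13)
  cmp <- rep(sprintf("c%02d", 1:50), each = 3)
  v <- rmat(150, 7, seed = 14)
  pm <- toyProfile(v, cmp)
  agg <- aggregateReplicates(pm, method = "median")
  oracle <- t(vapply(split(seq_along(cmp), cmp)[unique(cmp)],
                     function(ix) apply(v[ix, , drop = FALSE], 2,
                                        function(col) sort(col)[2]),
                     numeric(7)))
  expect_equal(unname(profileValues(agg)), unname(oracle),
               tolerance = 1e-12)
  expect_equal(unname(compoundIds(agg)), unique(cmp))
})

test_that("aggregation handles means, identity and idempotence", {
  v <- rbind(c(0, 0), c(2, 2))
  pm <- toyProfile(v, c("a", "a"))
  expect_equal(unname(profileValues(aggregateReplicates(pm, "mean"))),
               rbind(c(1, 1)))
  # one replicate per compound: output equals input
  single <- toyProfile(rmat(3, 4, seed = 2), c("a", "b", "c"),
                       rowIds = c("a", "b", "c"))
  agg1 <- aggregateReplicates(single)
  expect_equal(profileValues(agg1), profileValues(single))
  # aggregating an aggregate changes nothing
  big <- toyProfile(rmat(12, 5, seed = 3), rep(letters[1:4], each = 3))
  agg <- aggregateReplicates(big)
  expect_equal(profileValues(aggregateReplicates(agg)),
               profileValues(agg))
})

test_that("rowGroupAggregate covers uneven group sizes against apply()", {
  set.seed(31)
  groups <- rep(sprintf("g%d", 1:8), times = c(1, 2, 3, 4, 5, 6, 2, 3))
  v <- rmat(length(groups), 6, seed = 32)
  got <- rowGroupAggregate(v, groups, "median")
  oracle <- t(vapply(split(seq_along(groups), groups)[unique(groups)],
                     function(ix) apply(v[ix, , drop = FALSE], 2, median),
                     numeric(6)))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
})

test_that("bioactivity triplet CSV round trip preserves labels and family", {
  scr <- tinyScreen(seed = 5, labelDensity = 0.7)
  bio <- screenBioactivity(scr)
  dir <- withr::local_tempdir()
  writeBioactivityMatrix(bio, file.path(dir, "b.csv"),
                         familyPath = file.path(dir, "t.csv"))
  back <- readBioactivityMatrix(file.path(dir, "b.csv"),
                                familyPath = file.path(dir, "t.csv"))
  orig <- bioactivityLabels(bio)
  got <- bioactivityLabels(back)[rownames(orig), colnames(orig)]
  expect_equal(got, orig)
  expect_equal(taskFamily(back)[names(taskFamily(bio))], taskFamily(bio))
})
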