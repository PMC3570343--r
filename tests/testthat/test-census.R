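test_that("css parsing validates and truncates fold-family strings", {
  expect_equal(parse_css(c("c.37.1", "c.37.1.5", "b.40.4.2")),
               c("c.37.1", "c.37.1", "b.40.4"))
  expect_error(parse_css("37.1"), "malformed css")
  expect_error(parse_css("c.37"), "malformed css")
  expect_error(parse_css("C.37.1"), "malformed css")
})

test_that("assignment parsing collapses FF rows, prunes empty columns and checks ids", {
  met <- data.frame(proteome_id = c("P1", "P2"), supergroup = c("B", "E"))
  asn <- data.frame(proteome_id = c("P1", "P1", "P2"),
                    css = c("c.37.1", "c.37.1.5", "b.40.4"),
                    count = c(3, 2, 1))
  ab <- parse_assignments(asn, met)
  expect_equal(ab$g["P1", "c.37.1"], 5L)
  expect_equal(ab$g["P2", "c.37.1"], 0L)
  expect_equal(sort(colnames(ab$g)), c("b.40.4", "c.37.1"))
  expect_length(ab$pruned, 0)

  # a css observed only with count 0 is pruned and reported
  asn2 <- rbind(asn, data.frame(proteome_id = "P2", css = "d.58.1", count = 0))
  ab2 <- parse_assignments(asn2, met)
  expect_equal(ab2$pruned, "d.58.1")
  expect_false("d.58.1" %in% colnames(ab2$g))

  expect_error(parse_assignments(
    data.frame(proteome_id = "PX", css = "c.37.1", count = 1), met),
    "unknown proteome id")
  expect_error(parse_assignments(
    data.frame(proteome_id = "P1", css = "c.37.1", count = -1), met),
    "non-negative")

  empty <- parse_assignments(asn[0, ], met)
  expect_equal(dim(empty$g), c(2L, 0L))
})

test_that("occurrence thresholds abundance elementwise", {
  set.seed(3)
  g <- matrix(sample(0:9, 20, replace = TRUE), 5, 4,
              dimnames = list(paste0("p", 1:5), paste0("f", 1:4)))
  expect_equal(occurrence(g), (g > 0) + 0L, ignore_attr = FALSE)
  expect_true(all(occurrence(matrix(1:6, 2)) == 1))
})

test_that("distribution index is the fraction of scoped proteomes with the FSF", {
  ab <- toy_census()
  f <- distribution_index(ab)
  expect_equal(unname(f["c.37.1"]), 1)          # present everywhere
  expect_equal(unname(f["b.40.4"]), 4 / 7)
  fa <- distribution_index(ab, "A")
  expect_equal(unname(fa["a.1.1"]), 0)          # absent in scope
  # 3 of 8 scoped proteomes
  met <- data.frame(proteome_id = paste0("p", 1:8), supergroup = "B")
  asn <- data.frame(proteome_id = paste0("p", 1:3), css = "c.1.1", count = 1)
  expect_equal(unname(distribution_index(parse_assignments(asn, met), "B")),
               0.375)
  expect_error(distribution_index(ab, "X"), "scope")
})

test_that("group assignment matches a per-column brute-force membership scan", {
  set.seed(11)
  met <- data.frame(proteome_id = paste0("p", 1:8),
                    supergroup = rep(c("A", "B", "E", "V"), 2))
  g <- matrix(rpois(80, 0.8), 8, 10,
              dimnames = list(met$proteome_id, paste0("c.", 1:10, ".1")))
  g[, 1] <- 1  # guarantee at least one non-empty column
  ab <- domcensus:::new_abundance_matrix(g, domcensus:::validate_metadata(met))
  ab <- subset_census(ab)  # prune empties like the parser does
  grp <- assign_groups(ab)
  for (j in colnames(ab$g)) {
    expected <- paste(sort(unique(met$supergroup[ab$g[, j] > 0])), collapse = "")
    expect_equal(unname(grp$category[j]), expected)
  }
  expect_equal(sum(grp$tally), ncol(ab$g))   # tallies cover every retained FSF
  expect_length(grp$tally, 15)
  # an FSF in one archaeon and one virus only -> AV
  g2 <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
               dimnames = list(c("a1", "v1"), c("c.1.1", "c.2.1")))
  met2 <- data.frame(proteome_id = c("a1", "v1"), supergroup = c("A", "V"))
  grp2 <- assign_groups(domcensus:::new_abundance_matrix(
    g2, domcensus:::validate_metadata(met2)))
  expect_equal(unname(grp2$category), c("A", "V"))
  g2[1, 2] <- 1L
  grp3 <- assign_groups(domcensus:::new_abundance_matrix(
    g2, domcensus:::validate_metadata(met2)))
  expect_equal(unname(grp3$category["c.2.1"]), "AV")
})

test_that("reuse ratio is total count over distinct FSFs", {
  met <- data.frame(proteome_id = "p1", supergroup = "V")
  asn <- data.frame(proteome_id = "p1", css = c("c.1.1", "c.2.1", "c.3.1"),
                    count = c(4, 0, 2))
  ab <- parse_assignments(asn, met)
  expect_equal(reuse_ratio(ab, "p1"), 3)     # 6 / 2
  asn$count <- c(1, 1, 1)
  expect_equal(reuse_ratio(parse_assignments(asn, met), "p1"), 1)
  expect_error(reuse_ratio(ab, "nope"), "unknown proteome")
})

test_that("shared-vs-specific split returns scoped f distributions with medians", {
  ab <- toy_census()
  # V1 has only c.37.1; shared E set = {c.37.1}, specific = {b.40.4, a.1.1}
  s <- shared_vs_specific(ab, "E", "V")
  expect_equal(names(s$shared_f), "c.37.1")
  expect_equal(s$median_shared, 1)
  expect_equal(sort(names(s$specific_f)), c("a.1.1", "b.40.4"))
  expect_equal(s$median_specific, 1)  # both present in E1 and E2
  # empty shared set flagged as NA median
  met <- data.frame(proteome_id = c("e1", "v1"), supergroup = c("E", "V"))
  asn <- data.frame(proteome_id = c("e1", "v1"), css = c("c.1.1", "c.2.1"),
                    count = 1)
  s2 <- shared_vs_specific(parse_assignments(asn, met), "E", "V")
  expect_length(s2$shared_f, 0)
  expect_true(is.na(s2$median_shared))
})

test_that("census round-trips through TSV with its sidecar", {
  ab <- toy_census()
  tmp <- file.path(tempdir(), "census.tsv")
  write_census(ab, tmp)
  back <- read_census(tmp)
  expect_equal(back$g, ab$g)
  expect_equal(back$proteomes$supergroup, ab$proteomes$supergroup)
  expect_equal(occurrence(back), occurrence(ab))
  side <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(sum(unlist(side$tally)), ncol(ab$g))
  unlink(c(tmp, paste0(tmp, c(".json", ".meta.tsv"))))
})

test_that("distribution index grows when a harboring proteome enters the scope", {
  ab <- toy_census()
  f_all <- distribution_index(ab)
  sub <- subset_census(ab, proteomes = c("A1", "A2", "B1"), drop_empty = FALSE)
  f_sub <- distribution_index(sub)
  # adding E1 (which has a.1.1) can only increase f for a.1.1's count share
  sub2 <- subset_census(ab, proteomes = c("A1", "A2", "B1", "E1"),
                        drop_empty = FALSE)
  f_sub2 <- distribution_index(sub2)
  expect_true(f_sub2["a.1.1"] >= f_sub["a.1.1"])
})
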