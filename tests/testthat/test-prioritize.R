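test_that("rule grammar round-trips through parse and print", {
  rules <- c(
    "meja_up",
    "meja_up AND root_enriched",
    "(meja_up AND root_enriched) OR (root_specific AND periderm_enriched)",
    bhlhProspector:::DEFAULT_RULE,
    "meja_up OR root_enriched AND periderm_enriched")
  for (r in rules) {
    printed <- formatRule(parseRule(r))
    expect_identical(formatRule(parseRule(printed)), printed, info = r)
  }
})

test_that("rule evaluation respects precedence and malformed rules name a
           position", {
  flags <- list(meja_up = TRUE, root_enriched = FALSE,
                periderm_enriched = TRUE, root_specific = FALSE,
                subfamily_of_known_regulators = FALSE)
  # AND binds tighter than OR
  expect_true(evaluateRule(
    parseRule("meja_up OR root_enriched AND root_specific"), flags))
  expect_false(evaluateRule(
    parseRule("(meja_up OR root_enriched) AND root_specific"), flags))

  expect_error(parseRule("meja_up AND"), "position")
  expect_error(parseRule("threshhold"), "unknown flag")
  expect_error(parseRule("meja_up ) root_enriched"), "position")
  expect_error(parseRule(""), "position 1")
})

makeFlagFixture <- function() {
  members <- S4Vectors::DataFrame(
    name = paste0("bHLH", 1:4),
    gene_id = paste0("g", 1:4))
  spec <- data.frame(gene_id = paste0("g", 1:4),
                     specific_to = c("root", NA, NA, NA))
  list(members = members, spec = spec,
       sf = stats::setNames(c("A", "R", "A", "B"), members$name))
}

test_that("the default rule requires expression evidence", {
  fx <- makeFlagFixture()
  rep_ <- nominate(fx$members, fx$spec,
                   rootEnriched = "g2", peridermEnriched = "g1",
                   mejaUp = "g2", subfamilies = fx$sf,
                   regulatorSubfamilies = "R")
  expect_true(rep_$nominated[rep_$gene_id == "g2"])  # meja & root-enriched
  expect_true(rep_$nominated[rep_$gene_id == "g1"])  # specific & periderm
  expect_false(any(rep_$nominated[rep_$gene_id %in% c("g3", "g4")]))

  # subfamily membership alone never nominates
  noSpec <- data.frame(gene_id = fx$spec$gene_id,
                       specific_to = NA_character_)
  rep2 <- nominate(fx$members, noSpec,
                   rootEnriched = character(0),
                   peridermEnriched = character(0),
                   mejaUp = character(0), subfamilies = fx$sf,
                   regulatorSubfamilies = c("A", "B", "R"))
  expect_false(any(rep2$nominated))

  # report is sorted by evidence count then name and covers every member
  expect_equal(nrow(rep_), 4L)
  expect_false(is.unsorted(-rep_$evidence_count))
})

test_that("adding a flag never removes a nomination (monotone grammar)", {
  fx <- makeFlagFixture()
  base <- nominate(fx$members, fx$spec, rootEnriched = "g2",
                   peridermEnriched = "g1", mejaUp = "g2",
                   subfamilies = fx$sf)
  more <- nominate(fx$members, fx$spec, rootEnriched = c("g2", "g3"),
                   peridermEnriched = c("g1", "g3"),
                   mejaUp = c("g2", "g3"), subfamilies = fx$sf)
  expect_true(all(base$gene_id[base$nominated] %in%
                    more$gene_id[more$nominated]))
})
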