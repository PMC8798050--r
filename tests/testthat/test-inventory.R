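toy_metadata <- function() {
  data.frame(
    terminal_id = c("m1a", "m1b", "m2a", "m2b", "m3a"),
    subtribe = "S",
    subregion = c("NG", "AUS", "Sulawesi", "Moluccas", "NG"),
    region = c("Australian", "Australian", "Wallacea", "Wallacea",
               "Australian"),
    landmass = c("NG", "AUS", "Sulawesi", "Moluccas", "NG"),
    fragments = "cox1",
    stringsAsFactors = FALSE
  )
}

toy_barriers <- function() {
  as_barrier_map(data.frame(
    landmass_a = c("AUS", "AUS", "AUS", "NG", "NG", "Moluccas"),
    landmass_b = c("NG", "Sulawesi", "Moluccas", "Sulawesi", "Moluccas",
                   "Sulawesi"),
    barrier = c("shelf", "deep_sea", "deep_sea", "deep_sea", "deep_sea",
                "deep_sea")))
}

test_that("described ratios round half-up and handle zero denominators", {
  expect_equal(described_ratio(1434, 423), 3.39)
  expect_equal(described_ratio(33, 104), 0.32)
  expect_equal(described_ratio(0, 10), 0)
  expect_equal(described_ratio(1848, 1574), 1.17)
  expect_true(is.na(described_ratio(5, 0)))
  # half-up where round-half-even would differ
  expect_equal(described_ratio(125, 1000), 0.13)
  expect_equal(round_half_up(2.345, 2), 2.35)
})

test_that("region tables append totals and recomputable ratios", {
  counts <- data.frame(unit = c("u1", "u2", "u3"),
                       described = c(895L, 641L, 38L),
                       motus_2pct = c(1852L, 456L, 37L),
                       motus_5pct = c(1445L, 369L, 34L))
  tab <- region_table(counts)
  tot <- tab[tab$unit == "Total", ]
  expect_identical(tot$described, 1574L)
  expect_identical(tot$motus_2pct, 2345L)
  expect_identical(tot$motus_5pct, 1848L)
  expect_equal(tot$ratio_5pct, 1.17)
  # every emitted ratio is recomputable from the emitted integers
  expect_equal(tab$ratio_2pct, described_ratio(tab$motus_2pct,
                                               tab$described))
})

test_that("regional aggregation counts an mOTU in every region it
           occupies but once in the unique total", {
  md <- toy_metadata()
  part <- new_partition_for_test(
    c(m1a = 1L, m1b = 1L, m2a = 2L, m2b = 2L, m3a = 3L))
  described <- data.frame(unit = c("Australian", "Wallacea"),
                          described = c(3L, 1L))
  tab <- aggregate_regions(list(t5 = part), md, described)
  aus <- tab[tab$unit == "Australian", ]
  expect_identical(aus$motus_t5, 2L)            # clusters 1 and 3
  expect_identical(tab$motus_t5[tab$unit == "Wallacea"], 1L)
  occ_total <- tab[tab$unit == "Total (by occurrence)", ]
  uniq_total <- tab[tab$unit == "Total (unique mOTUs)", ]
  expect_identical(occ_total$motus_t5, 3L)
  expect_identical(uniq_total$motus_t5, 3L)
  expect_equal(uniq_total$ratio_t5, described_ratio(3, 4))

  # an mOTU spanning both regions raises by-occurrence but not the
  # unique total
  part2 <- new_partition_for_test(
    c(m1a = 1L, m1b = 1L, m2a = 1L, m2b = 2L, m3a = 3L))
  tab2 <- aggregate_regions(list(t5 = part2), md, described)
  expect_identical(tab2$motus_t5[tab2$unit == "Total (by occurrence)"], 4L)
  expect_identical(tab2$motus_t5[tab2$unit == "Total (unique mOTUs)"], 3L)
})

test_that("terminals without metadata are excluded with a warning", {
  md <- toy_metadata()
  part <- new_partition_for_test(
    c(m1a = 1L, m1b = 1L, ghost = 2L))
  expect_warning(got <- count_by_unit(part, md), "without metadata")
  expect_identical(unname(got$by_unit["Australian"]), 1L)
})

test_that("endemism marks mOTUs confined to one unit and matches a direct
           scan", {
  md <- toy_metadata()
  all_endemic <- new_partition_for_test(
    c(m1a = 1L, m2a = 2L, m2b = 3L, m3a = 4L, m1b = 5L))
  e1 <- endemism_table(all_endemic, md, level = "region")
  expect_equal(e1$global_proportion, 1.0)

  # cluster 1 spans two regions; 2 of 3 mOTUs are endemic
  part <- new_partition_for_test(
    c(m1a = 1L, m2a = 1L, m1b = 2L, m2b = 3L, m3a = 2L))
  e2 <- endemism_table(part, md, level = "region")
  expect_equal(e2$global_proportion, 2 / 3)

  set.seed(59)
  for (i in 1:10) {
    assign <- setNames(sample(1:3, 5, replace = TRUE), md$terminal_id)
    p <- new_partition_for_test(assign)
    e <- endemism_table(p, md, level = "landmass")
    # direct per-mOTU scan
    lm <- split(md$landmass, assign[md$terminal_id])
    expect_equal(e$global_proportion,
                 mean(vapply(lm, function(x) length(unique(x)) == 1L, NA)))
  }
})

test_that("turnover classifies spanned landmass pairs by barrier depth", {
  md <- toy_metadata()
  part <- new_partition_for_test(
    c(m1a = 1L, m1b = 1L,    # NG + AUS -> shelf
      m2a = 2L, m2b = 2L,    # Sulawesi + Moluccas -> deep sea
      m3a = 3L))             # single landmass, excluded
  tv <- turnover(part, md, toy_barriers())
  expect_identical(unname(tv$counts["shelf"]), 1L)
  expect_identical(unname(tv$counts["deep_sea"]), 1L)
  expect_identical(unname(tv$counts["contiguous"]), 0L)
  expect_identical(tv$n_multi_landmass, 2L)

  singles <- new_partition_for_test(
    c(m1a = 1L, m1b = 2L, m2a = 3L, m2b = 4L, m3a = 5L))
  expect_true(all(turnover(singles, md, toy_barriers())$counts == 0L))

  # duplicating terminals within an mOTU/landmass changes nothing
  md2 <- rbind(md, transform(md, terminal_id = paste0(terminal_id, "_dup")))
  part2 <- new_partition_for_test(
    setNames(rep(part$assignment, 2),
             c(names(part$assignment), paste0(names(part$assignment),
                                              "_dup"))))
  expect_identical(turnover(part2, md2, toy_barriers())$counts, tv$counts)
})

test_that("reports round-trip through TSV with totals intact", {
  tab <- region_table(data.frame(unit = c("a", "b"),
                                 described = c(10L, 20L),
                                 motus_x = c(15L, 12L)))
  dir <- withr::local_tempdir()
  render_report(list(regions = tab), dir)
  back <- read.delim(file.path(dir, "regions.tsv"),
                     stringsAsFactors = FALSE)
  expect_identical(back$described, tab$described)
  expect_identical(back$motus_x, tab$motus_x)
  expect_identical(back$described[back$unit == "Total"], 30L)
  expect_true(file.exists(file.path(dir, "summary.txt")))

  empty <- data.frame(unit = character(0), described = integer(0))
  render_report(list(empty = empty), dir)
  expect_identical(nrow(read.delim(file.path(dir, "empty.tsv"))), 0L)
})
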