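test_that("panel tables parse, validate and report malformed rows", {
  f <- write_panel_fixture(data.frame(
    kinase_id = c("K1", "K2", "K3"), compound_id = "C1",
    remaining_activity = c(12.5, 99.2, 50)))
  tab <- read_panel_table(f)
  expect_s3_class(tab, "panel_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$remaining_activity, c(12.5, 99.2, 50))

  # header-only file gives an empty table
  f2 <- tempfile(fileext = ".csv")
  writeLines("kinase_id,compound_id,remaining_activity", f2)
  expect_equal(nrow(read_panel_table(f2)), 0)

  # missing column and bad values are named precisely
  f3 <- write_panel_fixture(data.frame(kinase_id = "K1", compound_id = "C1"))
  expect_error(read_panel_table(f3), "remaining_activity")
  f4 <- tempfile(fileext = ".csv")
  writeLines(c("kinase_id,compound_id,remaining_activity",
               "K1,C1,12", "K2,C1,oops"), f4)
  expect_error(read_panel_table(f4), "line\\(s\\) 3")

  # configurable column names
  f5 <- tempfile(fileext = ".csv")
  writeLines(c("Kinase,Cmpd,Activity", "ampk,C1,8.1"), f5)
  tab5 <- read_panel_table(f5, kinase_col = "Kinase", compound_col = "Cmpd",
                           activity_col = "Activity")
  expect_equal(tab5$kinase_id, "ampk")
})

test_that("duplicate measurements collapse to means with SEM retained", {
  f <- write_panel_fixture(data.frame(
    kinase_id = c("K1", "K1", "K2"), compound_id = "C1",
    remaining_activity = c(40, 60, 70)))
  tab <- read_panel_table(f)
  expect_equal(nrow(tab), 2)
  k1 <- tab[tab$kinase_id == "K1", ]
  expect_equal(k1$remaining_activity, 50)
  expect_equal(k1$n_replicates, 2L)
  expect_equal(k1$sem, sd(c(40, 60)) / sqrt(2))
})

test_that("classification thresholds are boundary-inclusive", {
  f <- write_panel_fixture(data.frame(
    kinase_id = c("Kin50", "Kin99", "Kmid"), compound_id = "C1",
    remaining_activity = c(50.0, 99.0, 75)))
  g <- classify_groups(read_panel_table(f), "C1")
  expect_equal(g$inhibited, "Kin50")
  expect_equal(g$noninhibited, "Kin99")
  expect_equal(g$unclassified, "Kmid")
  expect_error(classify_groups(read_panel_table(f), "C1",
                               inhibited_cutoff = 99,
                               noninhibited_cutoff = 50), "strictly below")
  expect_error(classify_groups(read_panel_table(f), "absent"), "no panel")
})

test_that("classification matches a brute-force partition and is monotone", {
  set.seed(11)
  n <- 100
  ids <- sprintf("K%03d", seq_len(n))
  act <- round(runif(n, 0, 110), 2)
  tab <- data.frame(kinase_id = ids, compound_id = "C1",
                    remaining_activity = act, sem = NA_real_,
                    n_replicates = 1L)
  class(tab) <- c("panel_table", "data.frame")
  g <- classify_groups(tab, "C1")
  ref <- oracle_partition(ids, act, 50, 99)
  expect_setequal(g$inhibited, ref$inhibited)
  expect_setequal(g$noninhibited, ref$noninhibited)
  expect_setequal(g$unclassified, ref$unclassified)

  # partition property
  expect_equal(sort(c(g$inhibited, g$noninhibited, g$unclassified)),
               sort(ids))
  expect_length(intersect(g$inhibited, g$noninhibited), 0)

  # lowering the inhibited cutoff never adds an inhibited kinase
  for (lo in c(40, 30, 20, 10)) {
    g2 <- classify_groups(tab, "C1", inhibited_cutoff = lo)
    expect_true(all(g2$inhibited %in% g$inhibited))
    g <- g2
  }
})

test_that("overlap produces a consistent Venn partition", {
  mk <- function(inh, non, cmpd) {
    structure(list(inhibited = inh, noninhibited = non,
                   unclassified = character(0), inhibited_cutoff = 50,
                   noninhibited_cutoff = 99, compound_id = cmpd),
              class = "selectivity_groups")
  }
  ov <- overlap_groups(mk(c("x", "y"), "z", "A"), mk(c("y", "z"), "x", "B"))
  expect_equal(ov$only_a, "x")
  expect_equal(ov$only_b, "z")
  expect_equal(ov$both, "y")
  expect_equal(unname(ov$counts), c(1L, 1L, 1L))

  ident <- overlap_groups(mk(c("a", "b"), "c", "A"), mk(c("a", "b"), "c", "A"))
  expect_length(ident$only_a, 0)
  expect_length(ident$only_b, 0)

  # random sets against base set algebra; differing universes only warn
  set.seed(7)
  for (rep in 1:10) {
    u <- sprintf("K%02d", 1:30)
    a <- sample(u, 12)
    b <- sample(u, 9)
    ga <- mk(a, setdiff(u, a), "A")
    gb <- mk(b, setdiff(u, b), "B")
    ov <- overlap_groups(ga, gb)
    expect_setequal(ov$only_a, setdiff(a, b))
    expect_setequal(ov$only_b, setdiff(b, a))
    expect_setequal(ov$both, intersect(a, b))
    expect_setequal(c(ov$only_a, ov$only_b, ov$both), union(a, b))
  }
  expect_warning(overlap_groups(mk("x", "y", "A"), mk("x", "q", "B")),
                 "universes")
})

test_that("a synthetic 140-kinase table round-trips through write/read", {
  syn <- make_panel(n_inhibited = 7, n_noninhibited = 10, n_between = 123,
                    seed = 42)
  f <- tempfile(fileext = ".csv")
  write_panel_table(syn$table, f)
  back <- read_panel_table(f, sem_col = "sem")
  expect_equal(back$kinase_id, syn$table$kinase_id)
  expect_equal(back$remaining_activity, syn$table$remaining_activity,
               tolerance = 1e-12)
})
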