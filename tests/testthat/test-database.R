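test_that("ambiguity score is CA/CT with the documented extremes", {
  # all carbons uniquely assigned -> 0 (the adenosine-type case)
  expect_equal(ambiguity_score(list(C1 = 10, C2 = 20, C3 = 30)), 0)
  # all carbons multiply assigned -> 1 (the glucose-type case, anomers)
  expect_equal(ambiguity_score(list(C1 = c(10, 10.5), C2 = c(20, 21))), 1)
  # 2 ambiguous of 5 carbons -> 0.4
  expect_equal(ambiguity_score(list(C1 = 1, C2 = 2, C3 = 3,
                                    C4 = c(4, 4.1), C5 = c(5, 5.1))), 0.4)
  expect_error(ambiguity_score(list()), "undefined")
})

test_that("simulated peaks sit at the shift sums in the DQ dimension", {
  # one bond: peaks (10, 30) and (20, 30)
  pk <- simulate_compound_peaks(list(A = 10, B = 20), rbind(c("A", "B")))
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$cs_direct, c(10, 20))
  expect_equal(pk$cs_dq, c(30, 30))

  # 3-carbon chain 28.0 / 60.9 / 182.2 -> DQ rows at 88.9 and 243.1
  pk <- simulate_compound_peaks(
    list(C1 = 28.0, C2 = 60.9, C3 = 182.2),
    rbind(c("C1", "C2"), c("C2", "C3")))
  expect_equal(nrow(pk), 4)
  expect_setequal(round(unique(pk$cs_dq), 10), c(88.9, 243.1))
  # machine precision: DQ exactly equals the pairwise sums
  shifts <- c(C1 = 28.0, C2 = 60.9, C3 = 182.2)
  expect_identical(pk$cs_dq, shifts[pk$carbon] + shifts[pk$partner],
                   ignore_attr = TRUE)

  # one ambiguous carbon (2 shifts) bonded to a fixed carbon: 4 peaks
  # across 2 alternatives
  pk <- simulate_compound_peaks(list(A = c(10, 11), B = 20),
                                rbind(c("A", "B")))
  expect_equal(nrow(pk), 4)
  expect_equal(sort(unique(pk$alternative_index)), c(1, 2))

  expect_error(simulate_compound_peaks(list(A = 10), rbind(c("A", "Z"))),
               "schema")
})

test_that("db_compound validates and carries scores and peaks", {
  cmp <- db_compound("valine-like", "fx0003",
                     carbons = list(C1 = 177, C2 = 61.2, C3 = 29.9,
                                    C4 = c(17.5, 17.7), C5 = c(18.8, 19)),
                     bonds = rbind(c("C1", "C2"), c("C2", "C3"),
                                   c("C3", "C4"), c("C3", "C5")))
  expect_equal(cmp$ambiguity_score, 0.4)
  # 4 alternatives x 2 peaks per bond x 4 bonds
  expect_equal(nrow(cmp$sim_peaks), 4 * 2 * 4)
  expect_error(db_compound("x", "y", list(), rbind(c("A", "B"))),
               "zero carbons")
})

test_that("database build, filter, and JSON round trip", {
  db <- build_database(toy_library())
  expect_equal(length(db$compounds), 3)
  scores <- vapply(db$compounds, `[[`, numeric(1), "ambiguity_score")
  expect_equal(unname(scores), c(0, 0, 0.4))

  # threshold 1 is the identity; 0 keeps only unambiguous entries
  expect_equal(length(filter_by_ambiguity(db, 1)$compounds), 3)
  expect_equal(length(filter_by_ambiguity(db, 0)$compounds), 2)
  # a 0.5 threshold keeps scores {0, 0, 0.4} and drops higher ones
  db2 <- db
  db2$compounds$amb80 <- db_compound(
    "high-ambiguity", "amb80",
    carbons = list(C1 = c(10, 11), C2 = c(20, 21), C3 = c(30, 31),
                   C4 = c(40, 41), C5 = 50),
    bonds = rbind(c("C1", "C2")))
  expect_equal(db2$compounds$amb80$ambiguity_score, 0.8)
  kept <- filter_by_ambiguity(db2, 0.5)
  expect_setequal(names(kept$compounds), c("fx0001", "fx0002", "fx0003"))

  f <- withr::local_tempfile(fileext = ".json")
  write_database(db, f)
  back <- read_database(f)
  expect_equal(names(back$compounds), names(db$compounds))
  for (id in names(db$compounds)) {
    expect_equal(back$compounds[[id]]$carbons, db$compounds[[id]]$carbons)
    expect_equal(back$compounds[[id]]$ambiguity_score,
                 db$compounds[[id]]$ambiguity_score)
    expect_equal(back$compounds[[id]]$sim_peaks,
                 db$compounds[[id]]$sim_peaks)
  }
})

test_that("entries lacking bonds are skipped; duplicate ids renamed", {
  entries <- list(
    list(name = "ok", entry_id = "e1",
         carbons = list(C1 = 10, C2 = 20), bonds = rbind(c("C1", "C2"))),
    list(name = "no-bonds", entry_id = "e2",
         carbons = list(C1 = 10), bonds = matrix(character(0), ncol = 2)),
    list(name = "dup", entry_id = "e1",
         carbons = list(C1 = 30, C2 = 40), bonds = rbind(c("C1", "C2")))
  )
  expect_warning(expect_warning(db <- build_database(entries),
                                "no bonds"), "duplicate")
  expect_setequal(names(db$compounds), c("e1", "e1_2"))
})

test_that("NMR-STAR and table formats give the same compound", {
  star <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_fx_taurine",
    "_Entry.ID fxstar01",
    "_Entry.Title 'taurine-like'",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Atom_type",
    "  _Atom_chem_shift.Val",
    "  1 C1 C 36.4",
    "  2 C2 C 48.2",
    "  3 H1 H 3.2",
    "stop_",
    "loop_",
    "  _Chem_comp_bond.ID",
    "  _Chem_comp_bond.Atom_ID_1",
    "  _Chem_comp_bond.Atom_ID_2",
    "  1 C1 C2",
    "  2 C1 H1",
    "stop_"), star)
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# name: taurine-like", "# id: fxtab01",
               "carbon\tshifts\tbonded_to",
               "C1\t36.4\tC2", "C2\t48.2\t"), tab)
  db <- build_database(list(star, tab))
  a <- db$compounds$fxstar01
  b <- db$compounds$fxtab01
  expect_equal(a$carbons, b$carbons)
  expect_equal(a$bonds, b$bonds, ignore_attr = TRUE)
  expect_equal(a$ambiguity_score, 0)
  expect_equal(a$sim_peaks$cs_dq, b$sim_peaks$cs_dq)

  # an ambiguous methyl pair from a STAR file: two rows for one atom
  star2 <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_fx_methyl",
    "_Entry.ID fxstar02",
    "loop_",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Atom_type",
    "  _Atom_chem_shift.Val",
    "  C1 C 30.0",
    "  C2 C 17.5",
    "  C2 C 17.7",
    "stop_",
    "loop_",
    "  _Chem_comp_bond.Atom_ID_1",
    "  _Chem_comp_bond.Atom_ID_2",
    "  C1 C2",
    "stop_"), star2)
  db2 <- build_database(list(star2))
  cmp <- db2$compounds$fxstar02
  expect_equal(cmp$ambiguity_score, 0.5)
  expect_gt(max(cmp$sim_peaks$alternative_index), 1)
})
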