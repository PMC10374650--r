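trappe <- load_bundled()

test_that("the bundled TraPPE-UA subset has the published shape and clean validation", {
  expect_identical(
    unlist(glance(trappe)[paste0("n_", c("intermolecular", "bond", "angle",
                                         "torsion", "improper", "one_n", "special"))],
           use.names = FALSE),
    c(11L, 3L, 5L, 11L, 0L, 0L, 2L))
  issues <- validate_dataset(trappe)
  expect_identical(nrow(issues[issues$severity == "ERROR", ]), 0L)
  # every record carries a DOI-formatted reference
  refs <- unlist(purrr::map(c("intermolecular", "bond", "angle", "torsion", "special"),
                            ~ trappe[[.x]]$ref))
  expect_true(all(startsWith(refs, "10.")))
  # spot values straight from the printed tables
  inter <- trappe$intermolecular
  ch4 <- inter[inter$tag == "A-C-0-0", ]
  expect_equal(unlist(ch4[c("p1", "p2", "p3")], use.names = FALSE), c(0, 148, 3.73))
  oh <- inter[inter$tag == "Ak-O-2-1", ]
  expect_equal(unlist(oh[c("p1", "p2", "p3")], use.names = FALSE), c(-0.700, 93, 3.02))
  expect_true(all(is.na(trappe$bond$id2)))   # all TraPPE bonds are rigid
})

test_that("SQLite round trip is lossless and deterministic", {
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_database(trappe, db)
  back <- read_database(db, name = trappe$name)
  for (sec in c("intermolecular", "bond", "angle", "torsion", "improper",
                "one_n", "special")) {
    expect_equal(as.data.frame(back[[sec]]),
                 as.data.frame(ffdat:::sort_section(trappe[[sec]], sec)),
                 ignore_attr = TRUE)
  }
  # rigid bond rows come back as NA ids with the fixed length in p1
  cc <- back$bond[back$bond$tag1 == "X-C-X-1", ]
  expect_true(is.na(cc$id2))
  expect_equal(cc$p1, 1.54)
  # byte-determinism of the database file
  db2 <- withr::local_tempfile(fileext = ".sqlite")
  write_database(trappe, db2)
  back2 <- read_database(db2)
  expect_equal(as.data.frame(back2$torsion), as.data.frame(back$torsion))
})

test_that("a database missing a table is rejected with its name", {
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_database(trappe, db)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  DBI::dbExecute(con, 'DROP TABLE "special"')
  DBI::dbDisconnect(con)
  expect_error(read_database(db), "special", class = "ffdat_format_error")
})

test_that("workbook round trip is lossless, including via the database", {
  wb <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(trappe, wb)
  back <- read_workbook(wb, name = trappe$name)
  for (sec in c("intermolecular", "bond", "angle", "torsion", "improper",
                "one_n", "special")) {
    expect_equal(as.data.frame(back[[sec]]),
                 as.data.frame(ffdat:::sort_section(trappe[[sec]], sec)),
                 ignore_attr = TRUE)
  }
  # chained workbook -> database -> workbook conversion preserves records
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_database(back, db)
  wb2 <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(read_database(db), wb2)
  expect_equal(as.data.frame(read_workbook(wb2)$torsion),
               as.data.frame(back$torsion), ignore_attr = TRUE)
})

test_that("workbook reading reports missing columns and coerces numeric text", {
  # a sheet set with the angle sheet stripped of order2
  sheets <- purrr::imap(ffdat:::.ff_sections, function(spec, sec)
    ffdat:::section_to_storage(ffdat:::sort_section(trappe[[sec]], sec), sec))
  names(sheets) <- purrr::map_chr(names(sheets), ffdat:::db_table_name)
  broken <- sheets
  broken$angle <- broken$angle[setdiff(names(broken$angle), "order2")]
  wb <- withr::local_tempfile(fileext = ".xlsx")
  ffdat:::xlsx_write(broken, wb)
  expect_error(read_workbook(wb), "order2", class = "ffdat_format_error")

  # numeric cells stored as text parse leniently
  texty <- sheets
  texty$angle$p1 <- as.character(texty$angle$p1)
  texty$bond$order <- as.character(texty$bond$order)
  wb2 <- withr::local_tempfile(fileext = ".xlsx")
  ffdat:::xlsx_write(texty, wb2)
  back <- read_workbook(wb2)
  expect_equal(back$angle$p1, ffdat:::sort_section(trappe$angle, "angle")$p1)
  expect_identical(back$bond$order, rep(1L, 3))
})

test_that("validation flags arity mismatches, duplicates and bad tags", {
  bad_angle <- trappe$angle
  bad_angle$p3[1] <- 99        # harmonic angle takes exactly two parameters
  ds <- ff_dataset("bad", angle = bad_angle)
  issues <- validate_dataset(ds)
  expect_true(any(issues$severity == "ERROR" &
                  grepl("expects 2 parameter", issues$message)))

  dup <- trappe$bond[c(1, 1), ]
  dup$tag1[2] <- trappe$bond$tag2[1]; dup$tag2[2] <- trappe$bond$tag1[1]
  ds2 <- ff_dataset("dup", bond = dup)
  issues2 <- validate_dataset(ds2)
  expect_true(any(grepl("duplicate", issues2$message)))
  expect_error(write_database(ds2, withr::local_tempfile(fileext = ".sqlite")),
               class = "ffdat_validation_error")

  bad_tag <- trappe$intermolecular
  bad_tag$tag[1] <- "A-C-2"
  issues3 <- validate_dataset(ff_dataset("t", intermolecular = bad_tag))
  expect_true(any(issues3$severity == "ERROR" & grepl("tag", issues3$message)))

  odd_group <- trappe$intermolecular
  odd_group$tag[1] <- "Qz-C-0-0"
  issues4 <- validate_dataset(ff_dataset("g", intermolecular = odd_group))
  expect_true(any(issues4$severity == "WARNING" & grepl("Qz", issues4$message)))
})

test_that("validation is idempotent and order-independent", {
  set.seed(11)
  shuffled <- ff_dataset("shuffled", units = trappe$units,
    intermolecular = trappe$intermolecular[sample(11), ],
    bond = trappe$bond[sample(3), ],
    angle = trappe$angle[sample(5), ],
    torsion = trappe$torsion[sample(11), ],
    special = trappe$special[sample(2), ])
  i1 <- validate_dataset(shuffled)
  i2 <- validate_dataset(shuffled)
  expect_identical(i1, i2)
  expect_identical(nrow(i1[i1$severity == "ERROR", ]), 0L)
})

test_that("dataset text rendering covers every section", {
  txt <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_text(trappe, txt)
  lines <- readLines(txt)
  for (tbl in c("intermolecular", "bond", "angle", "torsion", "improper",
                "1n_potential", "special")) {
    expect_true(any(lines == sprintf("## %s", tbl)))
  }
  expect_true(any(grepl("none\t1.54", lines, fixed = TRUE)))
})
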