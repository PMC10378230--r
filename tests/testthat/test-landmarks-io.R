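write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("CSV landmark parsing resolves names, synonyms and midpoints", {
  tpl <- template_landmarks()
  path <- tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z",
               vapply(seq_len(nrow(tpl)), function(i) {
                 sprintf("%s,%.10f,%.10f,%.10f",
                         tpl$name[i], tpl$x[i], tpl$y[i], tpl$z[i])
               }, "")), path)
  lm <- read_landmarks_3d(path)
  expect_s3_class(lm, "landmarks_3d")
  expect_equal(lmk(lm, "mCo"), (lmk(lm, "rCo") + lmk(lm, "lCo")) / 2)
  expect_equal(lmk(lm, "mAoc"), (lmk(lm, "rAoc") + lmk(lm, "lAoc")) / 2)

  # Synonym + case-insensitive resolution.
  syn <- c("name,x,y,z", "Basion,0,0,0",
           vapply(which(tpl$name != "Ba"), function(i) {
             sprintf("%s,%.4f,%.4f,%.4f",
                     toupper(tpl$name[i]), tpl$x[i], tpl$y[i], tpl$z[i])
           }, ""))
  lm2 <- read_landmarks_3d(write_tmp(syn, ".csv"))
  expect_equal(lmk(lm2, "Ba"), c(0, 0, 0))

  # Missing landmark is named in the error.
  drop_pns <- tpl[tpl$name != "PNS", ]
  p3 <- write_tmp(c("name,x,y,z",
                    sprintf("%s,%g,%g,%g", drop_pns$name, drop_pns$x,
                            drop_pns$y, drop_pns$z)), ".csv")
  expect_error(read_landmarks_3d(p3), "PNS",
               class = "trk_error_missing_landmark")

  # Malformed row reports its line number.
  bad <- write_tmp(c("name,x,y,z", "Ba,1,2"), ".csv")
  expect_error(read_landmarks_3d(bad), "line 2",
               class = "trk_error_malformed")
})

test_that("JSON and FCSV dialects parse and frames convert involutively", {
  tpl <- template_landmarks()
  obj <- lapply(seq_len(nrow(tpl)), function(i) c(tpl$x[i], tpl$y[i], tpl$z[i]))
  names(obj) <- tpl$name
  jp <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, jp, digits = NA)
  lm_json <- read_landmarks_3d(jp)
  expect_equal(lmk(lm_json, "rMCF"), c(25, 45, 18))

  # FCSV with an LPS header: x and y flip on entry.
  fcsv <- c("# Markups fiducial file version = 4.11",
            "# CoordinateSystem = LPS",
            "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
            vapply(seq_len(nrow(tpl)), function(i) {
              sprintf("vtkMRMLMarkupsFiducialNode_%d,%g,%g,%g,0,0,0,1,1,1,0,%s,,",
                      i, -tpl$x[i], -tpl$y[i], tpl$z[i], tpl$name[i])
            }, ""))
  lm_fcsv <- read_landmarks_3d(write_tmp(fcsv, ".fcsv"))
  expect_equal(lmk(lm_fcsv, "rMCF"), c(25, 45, 18))
  expect_equal(lmk(lm_fcsv, "Ba"), c(0, 0, 0))

  # LPS -> RAS -> LPS restores coordinates exactly (involution).
  lm0 <- template_lm3d()
  prim <- lm0[!lm0$derived, ]
  flip <- prim
  flip$x <- -flip$x; flip$y <- -flip$y
  cp <- write_tmp(c("name,x,y,z",
                    sprintf("%s,%.17g,%.17g,%.17g", flip$name, flip$x,
                            flip$y, flip$z)), ".csv")
  lm_lps <- read_landmarks_3d(cp, frame = "LPS")
  expect_equal(lmk(lm_lps, "rGo"), lmk(lm0, "rGo"))
})

test_that("round trips through CSV and JSON are lossless", {
  withr::with_seed(5, {
    s <- generate_subject(subject_params(noise_sd = 0.8, asymmetry = 1,
                                         seed = 99))
  })
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_landmarks(s$lm3d, path, format = fmt)
    back <- read_landmarks_3d(path)
    expect_equal(back$x, s$lm3d$x, tolerance = 1e-12)
    expect_equal(back$y, s$lm3d$y, tolerance = 1e-12)
    expect_equal(back$z, s$lm3d$z, tolerance = 1e-12)
  }
  path2 <- tempfile(fileext = ".csv")
  write_landmarks(s$lm2d, path2)
  back2 <- read_landmarks_2d(path2)
  expect_equal(back2$x, s$lm2d$x, tolerance = 1e-12)
})

test_that("2D parsing flags missing and duplicate landmarks", {
  expect_error(read_landmarks_2d(write_tmp(
    c("name,x,y", "SE,40,30", "Ptm,40,10", "Go,0,-50", "Poc,30,-40",
      "Aoc,55,-38"), ".csv")),
    "Ar", class = "trk_error_missing_landmark")
  expect_error(read_landmarks_2d(write_tmp(
    c("name,x,y", "SE,40,30", "SE,41,31", "Ar,0,0", "Ptm,40,10",
      "Go,0,-50", "Poc,30,-40", "Aoc,55,-38"), ".csv")),
    class = "trk_error_duplicate_landmark")
  expect_warning(as_landmarks_2d(rbind(
    data.frame(name = c("SE", "Ar", "Ptm", "Go", "Poc", "Aoc"),
               x = c(40, 0, 40, 0, 30, 55), y = c(30, 0, 10, -50, -40, -38)),
    data.frame(name = "Mystery", x = 1, y = 1))),
    class = "trk_warning_unknown_landmark")
})

test_that("validate_landmarks reports degeneracies and implausibilities as findings", {
  expect_identical(nrow(validate_landmarks(template_lm3d())), 0L)

  tpl <- template_landmarks()
  tpl$x[tpl$name == "rGo"] <- -45   # collapse rGo onto lGo
  tpl$y[tpl$name == "rGo"] <- 25
  tpl$z[tpl$name == "rGo"] <- -55
  f <- validate_landmarks(as_landmarks_3d(tpl))
  expect_true(any(f$severity == "error" & grepl("MR plane", f$message)))

  tpl2 <- template_landmarks()
  i_r <- tpl2$name == "rCo"; i_l <- tpl2$name == "lCo"
  tpl2$x[i_r] <- -50; tpl2$x[i_l] <- 50    # swapped laterality
  f2 <- validate_landmarks(as_landmarks_3d(tpl2))
  expect_true(any(f2$code == "laterality"))

  tpl3 <- template_landmarks()
  tpl3$x[tpl3$name == "rMCF"] <- 500       # implausible distance
  f3 <- validate_landmarks(as_landmarks_3d(tpl3))
  expect_true(any(f3$code == "implausible_distance"))
})

test_that("analysis reports round-trip through JSON and refuse non-finite angles", {
  rep <- analyze_subject(template_lm3d(), subject = "tpl")
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$subject, rep$subject)
  expect_equal(back$mode, rep$mode)
  expect_equal(back$angles$value, rep$angles$value, tolerance = 1e-12)
  expect_equal(unlist(back$self_check), unlist(rep$self_check),
               tolerance = 1e-12)
  expect_equal(back$points$SEn, rep$points$SEn, tolerance = 1e-12)
  expect_equal(back$input_digest, rep$input_digest)

  rep_bad <- rep
  rep_bad$self_check$`MCFn^PMn` <- NaN
  expect_error(write_report(rep_bad, tempfile(fileext = ".json")),
               class = "trk_error_validation")

  expect_error(read_report(tempfile(fileext = ".json")),
               class = "trk_error_io")
})
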