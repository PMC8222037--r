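# imzML/ibd writing and reading: round trips, integrity checks, and a
# cross-check against the independent pyimzML parser.

gridFixture <- function() {
  makeGrid(
    coords = cbind(x = c(1L, 2L, 3L, 1L, 3L), y = c(1L, 1L, 1L, 2L, 3L)),
    peaks = list(
      cbind(c(200.1, 300.25, 450.5), c(10, 20.5, 30)),
      cbind(numeric(0), numeric(0)),               # scanned, empty spectrum
      cbind(c(199.9999, 640.0001), c(1e6, 0.001)),
      cbind(564.3068, 100),
      cbind(c(210.5, 210.6, 210.7), c(5, 6, 7))),
    mzRange = c(185, 650), pixelSize = c(400, 400))
}

test_that("write/read round trip is the identity at float64, both modes", {
  g <- gridFixture()
  for (mode in c("processed", "continuous")) {
    gm <- g
    if (mode == "continuous") {
      # continuous requires one shared axis
      ax <- c(200, 300, 400)
      gm <- makeGrid(cbind(x = 1:3, y = 1L),
                     list(cbind(ax, c(1, 2, 3)), cbind(ax, c(4, 5, 6)),
                          cbind(ax, c(0, 0, 9))),
                     mzRange = c(185, 650))
    }
    d <- withr::local_tempdir()
    writeImzML(gm, file.path(d, "rt"), mode = mode,
               mzPrecision = "float64", intensityPrecision = "float64")
    back <- readImzML(file.path(d, "rt.imzML"))
    expect_identical(back@mz, gm@mz)
    expect_identical(back@intensity, gm@intensity)
    expect_identical(pixelCoords(back), pixelCoords(gm))
    expect_identical(back@metadata$binary_mode, mode)
    expect_equal(back@pixelSize, gm@pixelSize)
  }
})

test_that("default precisions keep m/z exact and intensities near-exact", {
  set.seed(7)
  g <- randomGrid(nPix = 100L, maxPeaks = 20L)
  d <- withr::local_tempdir()
  writeImzML(g, file.path(d, "f32"), mode = "processed")
  back <- readImzML(file.path(d, "f32.imzML"))
  expect_identical(back@mz, g@mz)  # m/z stays float64
  relerr <- mapply(function(a, b) {
    if (!length(a)) return(0)
    max(abs(a - b) / pmax(abs(b), 1e-12))
  }, back@intensity, g@intensity)
  expect_lt(max(relerr), 1e-6)
})

test_that("writing the same grid twice gives byte-identical files", {
  g <- gridFixture()
  d <- withr::local_tempdir()
  writeImzML(g, file.path(d, "a"))
  writeImzML(g, file.path(d, "b"))
  expect_identical(unname(tools::md5sum(file.path(d, "a.ibd"))),
                   unname(tools::md5sum(file.path(d, "b.ibd"))))
  a <- readLines(file.path(d, "a.imzML"))
  b <- readLines(file.path(d, "b.imzML"))
  expect_identical(a, b)
})

test_that("integrity violations are rejected with informative errors", {
  g <- gridFixture()
  d <- withr::local_tempdir()
  writeImzML(g, file.path(d, "x"))

  # missing ibd
  file.rename(file.path(d, "x.ibd"), file.path(d, "x.ibd.bak"))
  expect_error(readImzML(file.path(d, "x.imzML")), "missing ibd")
  file.rename(file.path(d, "x.ibd.bak"), file.path(d, "x.ibd"))

  # corrupt the UUID head: error must name both UUIDs
  ibd <- readBin(file.path(d, "x.ibd"), "raw",
                 file.size(file.path(d, "x.ibd")))
  orig <- ibd
  ibd[1] <- xor(ibd[1], as.raw(0xFF))
  writeBin(ibd, file.path(d, "x.ibd"))
  err <- tryCatch(readImzML(file.path(d, "x.imzML")),
                  error = conditionMessage)
  expect_match(err, "UUID mismatch")
  expect_match(err, paste(format(orig[1:16]), collapse = ""))
  expect_match(err, paste(format(ibd[1:16]), collapse = ""))

  # corrupt a payload byte: checksum must catch it
  ibd <- orig
  ibd[length(ibd)] <- xor(ibd[length(ibd)], as.raw(0x01))
  writeBin(ibd, file.path(d, "x.ibd"))
  expect_error(readImzML(file.path(d, "x.imzML")), "MD5 mismatch")
  writeBin(orig, file.path(d, "x.ibd"))

  # continuous mode with heterogeneous axes is refused at write time
  expect_error(writeImzML(g, file.path(d, "y"), mode = "continuous"),
               "identical m/z axes")
})

test_that("non-ascending m/z arrays are rejected, not reordered", {
  g <- makeGrid(cbind(x = 1L, y = 1L), list(cbind(c(200, 300), c(1, 2))),
                mzRange = c(185, 650))
  d <- withr::local_tempdir()
  writeImzML(g, file.path(d, "z"), mzPrecision = "float64")
  # swap the two m/z values directly in the ibd (offset 16, float64 LE)
  con <- file(file.path(d, "z.ibd"), "r+b")
  seek(con, 16, rw = "write")
  writeBin(c(300, 200), con, size = 8, endian = "little")
  close(con)
  # drop the (now stale) checksum so the ordering check itself is exercised
  xml <- readLines(file.path(d, "z.imzML"))
  writeLines(xml[!grepl("IMS:1000090", xml)], file.path(d, "z.imzML"))
  expect_error(readImzML(file.path(d, "z.imzML")),
               "not strictly ascending")
})

test_that("pyimzML (independent parser) reads our files identically", {
  g <- gridFixture()
  d <- withr::local_tempdir()
  writeImzML(g, file.path(d, "py"), mode = "processed",
             mzPrecision = "float64", intensityPrecision = "float64")
  script <- file.path(d, "dump.py")
  writeLines(c(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "out = []",
    "for i, c in enumerate(p.coordinates):",
    "    mz, it = p.getspectrum(i)",
    "    out.append({'x': int(c[0]), 'y': int(c[1]),",
    "                'mz': [float(v) for v in mz],",
    "                'int': [float(v) for v in it]})",
    "print(json.dumps(out))"), script)
  res <- system2("python", c(script, file.path(d, "py.imzML")),
                 stdout = TRUE, stderr = FALSE)
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""),
                               simplifyVector = FALSE)
  expect_length(parsed, nPixels(g))
  for (i in seq_along(parsed)) {
    expect_identical(as.integer(c(parsed[[i]]$x, parsed[[i]]$y)),
                     unname(pixelCoords(g)[i, ]))
    expect_equal(as.numeric(unlist(parsed[[i]]$mz)), g@mz[[i]],
                 tolerance = 1e-12)
    expect_equal(as.numeric(unlist(parsed[[i]]$int)), g@intensity[[i]],
                 tolerance = 1e-12)
  }
})
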