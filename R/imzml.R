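# imzML 1.1 + ibd I/O for centroided MSI data. Both binary layouts are
# supported: "continuous" (one shared m/z axis) and "processed" (per-pixel
# m/z axes). The ibd starts with a 16-byte UUID that must match the UUID
# declared in the XML; the writer derives the UUID from the MD5 of the array
# payload, so identical grids produce byte-identical file pairs, and records
# the imzML-standard MD5 checksum of the whole ibd.

.IMZML_XML_HEADER <- paste0(
  '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
  '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
  '  <cvList count="3">\n',
  '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="1.3.1" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
  '    <cv id="UO" fullName="Unit Ontology" version="1.15" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
  '    <cv id="IMS" fullName="Imaging MS Ontology" version="0.9.1" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
  '  </cvList>\n')

.cvp <- function(ref, acc, name, value = NULL, unit = NULL) {
  v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
  u <- if (is.null(unit)) "" else
    sprintf(' unitCvRef="%s" unitAccession="%s" unitName="%s"',
            unit[1], unit[2], unit[3])
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s%s/>',
          ref, acc, name, v, u)
}

.fmtUuid <- function(hex32) {
  paste(substr(hex32, 1, 8), substr(hex32, 9, 12), substr(hex32, 13, 16),
        substr(hex32, 17, 20), substr(hex32, 21, 32), sep = "-")
}

.imzmlPaths <- function(path) {
  if (grepl("\\.imzML$", path, ignore.case = TRUE)) {
    list(imzml = path, ibd = sub("\\.imzML$", ".ibd", path,
                                 ignore.case = TRUE))
  } else {
    list(imzml = paste0(path, ".imzML"), ibd = paste0(path, ".ibd"))
  }
}

#' Write a SpectrumGrid as an imzML/ibd file pair
#'
#' Emits standard-conformant imzML 1.1 (readable by third-party parsers such
#' as pyimzML) plus the external binary ibd. `write -> read` is the identity
#' on arrays and coordinates at `"float64"` encoding; the `"float32"`
#' intensity default matches typical Orbitrap centroid exports.
#'
#' @param grid A [SpectrumGrid-class].
#' @param path Output path; `".imzML"` is appended if absent, the sibling
#'   `.ibd` is written next to it.
#' @param mode `"processed"` (per-pixel m/z axes, default) or `"continuous"`
#'   (one shared axis; an error if pixels have differing m/z arrays).
#' @param mzPrecision,intensityPrecision `"float64"` or `"float32"`.
#' @return Invisibly, the two file paths.
#' @export
writeImzML <- function(grid, path, mode = c("processed", "continuous"),
                       mzPrecision = c("float64", "float32"),
                       intensityPrecision = c("float32", "float64")) {
  stopifnot(is(grid, "SpectrumGrid"))
  mode <- match.arg(mode)
  mzPrecision <- match.arg(mzPrecision)
  intensityPrecision <- match.arg(intensityPrecision)
  p <- .imzmlPaths(path)
  n <- nPixels(grid)
  mzSize <- if (mzPrecision == "float64") 8L else 4L
  intSize <- if (intensityPrecision == "float64") 8L else 4L

  if (mode == "continuous" && n > 1L) {
    ref <- grid@mz[[1]]
    same <- vapply(grid@mz, function(m) identical(m, ref), TRUE)
    if (!all(same))
      stop("continuous mode requires identical m/z axes across pixels; ",
           sum(!same), " pixel(s) differ (use mode = 'processed')")
  }

  # --- binary payload + per-spectrum offsets --------------------------------
  lens <- lengths(grid@mz)
  mzOffset <- intOffset <- numeric(n)
  con <- rawConnection(raw(0), "wb")
  pos <- 16  # after the UUID
  if (mode == "continuous" && n > 0L) {
    writeBin(as.numeric(grid@mz[[1]]), con, size = mzSize,
             endian = "little")
    mzOffset[] <- pos
    pos <- pos + lens[1] * mzSize
    for (i in seq_len(n)) {
      writeBin(as.numeric(grid@intensity[[i]]), con, size = intSize,
               endian = "little")
      intOffset[i] <- pos
      pos <- pos + lens[i] * intSize
    }
  } else {
    for (i in seq_len(n)) {
      writeBin(as.numeric(grid@mz[[i]]), con, size = mzSize,
               endian = "little")
      mzOffset[i] <- pos
      pos <- pos + lens[i] * mzSize
      writeBin(as.numeric(grid@intensity[[i]]), con, size = intSize,
               endian = "little")
      intOffset[i] <- pos
      pos <- pos + lens[i] * intSize
    }
  }
  payload <- rawConnectionValue(con)
  close(con)

  tf <- tempfile()
  writeBin(payload, tf)
  uuidHex <- unname(tools::md5sum(tf))
  unlink(tf)
  uuidRaw <- as.raw(strtoi(substring(uuidHex,
                                     seq(1, 31, 2), seq(2, 32, 2)), 16L))
  writeBin(c(uuidRaw, payload), p$ibd)
  ibdMd5 <- unname(tools::md5sum(p$ibd))

  # --- XML ------------------------------------------------------------------
  modeAcc <- if (mode == "continuous")
    .cvp("IMS", "IMS:1000030", "continuous") else
    .cvp("IMS", "IMS:1000031", "processed")
  polAcc <- if (identical(grid@polarity, "negative"))
    .cvp("MS", "MS:1000129", "negative scan") else
    .cvp("MS", "MS:1000130", "positive scan")
  prec <- function(kind) {
    if (kind == "float64") .cvp("MS", "MS:1000523", "64-bit float")
    else .cvp("MS", "MS:1000521", "32-bit float")
  }
  maxX <- if (n) max(grid@coords[, 1]) else 0L
  maxY <- if (n) max(grid@coords[, 2]) else 0L

  head <- c(
    .IMZML_XML_HEADER,
    '  <fileDescription>\n    <fileContent>\n',
    paste0('      ', .cvp("MS", "MS:1000579", "MS1 spectrum"), '\n'),
    paste0('      ', .cvp("MS", "MS:1000127", "centroid spectrum"), '\n'),
    paste0('      ', modeAcc, '\n'),
    paste0('      ', .cvp("IMS", "IMS:1000080",
                          "universally unique identifier",
                          paste0("{", .fmtUuid(uuidHex), "}")), '\n'),
    paste0('      ', .cvp("IMS", "IMS:1000090", "ibd MD5",
                          toupper(ibdMd5)), '\n'),
    '    </fileContent>\n  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    '    <referenceableParamGroup id="mzArray">\n',
    paste0('      ', .cvp("MS", "MS:1000576", "no compression"), '\n'),
    paste0('      ', .cvp("MS", "MS:1000514", "m/z array", "",
                          c("MS", "MS:1000040", "m/z")), '\n'),
    paste0('      ', .cvp("IMS", "IMS:1000101", "external data", "true"), '\n'),
    paste0('      ', prec(mzPrecision), '\n'),
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    paste0('      ', .cvp("MS", "MS:1000576", "no compression"), '\n'),
    paste0('      ', .cvp("MS", "MS:1000515", "intensity array", "",
                          c("MS", "MS:1000131", "number of counts")), '\n'),
    paste0('      ', .cvp("IMS", "IMS:1000101", "external data", "true"), '\n'),
    paste0('      ', prec(intensityPrecision), '\n'),
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <softwareList count="1">\n',
    '    <software id="steroidMSI" version="0.1.0"/>\n',
    '  </softwareList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scanSettings1">\n',
    paste0('      ', .cvp("IMS", "IMS:1000042", "max count of pixels x",
                          maxX), '\n'),
    paste0('      ', .cvp("IMS", "IMS:1000043", "max count of pixels y",
                          maxY), '\n'),
    paste0('      ', .cvp("IMS", "IMS:1000046", "pixel size (x)",
                          grid@pixelSize[1],
                          c("UO", "UO:0000017", "micrometer")), '\n'),
    paste0('      ', .cvp("IMS", "IMS:1000047", "pixel size y",
                          grid@pixelSize[2],
                          c("UO", "UO:0000017", "micrometer")), '\n'),
    paste0('      <userParam name="lowest observed m/z" value="',
           format(grid@mzRange[1], digits = 15), '"/>\n'),
    paste0('      <userParam name="highest observed m/z" value="',
           format(grid@mzRange[2], digits = 15), '"/>\n'),
    '    </scanSettings>\n  </scanSettingsList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1"/>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="dp1">\n',
    '      <processingMethod order="1" softwareRef="steroidMSI">\n',
    paste0('        ', .cvp("MS", "MS:1000544", "Conversion to mzML"), '\n'),
    '      </processingMethod>\n',
    '    </dataProcessing>\n  </dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="dp1">\n',
            n)
  )

  specXml <- character(n)
  for (i in seq_len(n)) {
    specXml[i] <- paste0(
      sprintf('      <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">\n',
              i, lens[i], i - 1L),
      '        ', .cvp("MS", "MS:1000579", "MS1 spectrum"), '\n',
      '        ', .cvp("MS", "MS:1000127", "centroid spectrum"), '\n',
      '        ', polAcc, '\n',
      '        <scanList count="1">\n',
      '          ', .cvp("MS", "MS:1000795", "no combination"), '\n',
      '          <scan>\n',
      '            ', .cvp("IMS", "IMS:1000050", "position x",
                           grid@coords[i, 1]), '\n',
      '            ', .cvp("IMS", "IMS:1000051", "position y",
                           grid@coords[i, 2]), '\n',
      '          </scan>\n',
      '        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      '            ', .cvp("IMS", "IMS:1000103", "external array length",
                           lens[i]), '\n',
      '            ', .cvp("IMS", "IMS:1000104", "external encoded length",
                           sprintf("%.0f", lens[i] * mzSize)), '\n',
      '            ', .cvp("IMS", "IMS:1000102", "external offset",
                           sprintf("%.0f", mzOffset[i])), '\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      '            ', .cvp("IMS", "IMS:1000103", "external array length",
                           lens[i]), '\n',
      '            ', .cvp("IMS", "IMS:1000104", "external encoded length",
                           sprintf("%.0f", lens[i] * intSize)), '\n',
      '            ', .cvp("IMS", "IMS:1000102", "external offset",
                           sprintf("%.0f", intOffset[i])), '\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>\n')
  }

  tail <- '    </spectrumList>\n  </run>\n</mzML>\n'
  out <- file(p$imzml, "wb")  # binary: byte-identical across platforms
  writeBin(charToRaw(paste0(paste0(head, collapse = ""),
                            paste0(specXml, collapse = ""), tail)), out)
  close(out)
  invisible(list(imzml = p$imzml, ibd = p$ibd))
}

# Namespace-aware xpath helper: mzML uses a default namespace, which xml2
# maps to the prefix "d1". Stripping namespaces is avoided on purpose (it
# walks the whole node tree, which is slow for rasters of thousands of
# spectra); instead element names in our xpath templates are prefixed.
.nsPrefix <- function(doc) {
  if ("d1" %in% names(xml2::xml_ns(doc))) "d1:" else ""
}

.xmlCvValue <- function(doc, pfx, acc, where = "") {
  node <- xml2::xml_find_first(
    doc, sprintf("%s//%scvParam[@accession='%s']", where, pfx, acc))
  if (inherits(node, "xml_missing")) NULL else xml2::xml_attr(node, "value")
}

#' Read an imzML/ibd file pair into a SpectrumGrid
#'
#' Accepts continuous- and processed-mode centroided data. The 16-byte UUID
#' at the head of the ibd must match the UUID declared in the XML; the ibd
#' MD5 checksum is verified when declared. Profile-mode data and
#' non-ascending m/z arrays are rejected rather than silently fixed.
#'
#' @param path Path to the `.imzML` file (the sibling `.ibd` is located
#'   automatically).
#' @return A [SpectrumGrid-class].
#' @export
readImzML <- function(path) {
  p <- .imzmlPaths(path)
  if (!file.exists(p$imzml)) stop("imzML file not found: ", p$imzml)
  if (!file.exists(p$ibd))
    stop("missing ibd file: ", p$ibd, " (required sibling of ", p$imzml, ")")
  doc <- xml2::read_xml(p$imzml)
  pfx <- .nsPrefix(doc)

  fc <- sprintf("//%sfileDescription/%sfileContent", pfx, pfx)
  isCont <- !is.null(.xmlCvValue(doc, pfx, "IMS:1000030", fc))
  isProc <- !is.null(.xmlCvValue(doc, pfx, "IMS:1000031", fc))
  if (!isCont && !isProc)
    stop("imzML declares neither continuous nor processed binary mode")
  if (!is.null(.xmlCvValue(doc, pfx, "MS:1000128", fc)))
    stop("profile-mode imzML is not supported (centroided data expected)")

  declUuid <- .xmlCvValue(doc, pfx, "IMS:1000080", fc)
  if (is.null(declUuid)) stop("imzML lacks the ibd UUID (IMS:1000080)")
  declUuid <- tolower(gsub("[{}-]", "", declUuid))
  declMd5 <- .xmlCvValue(doc, pfx, "IMS:1000090", fc)

  ibdSize <- file.size(p$ibd)
  con <- file(p$ibd, "rb")
  on.exit(close(con), add = TRUE)
  ibdUuid <- paste(format(readBin(con, "raw", 16L)), collapse = "")
  if (!identical(ibdUuid, declUuid))
    stop(sprintf("UUID mismatch: imzML declares %s but ibd starts with %s",
                 declUuid, ibdUuid))
  if (!is.null(declMd5)) {
    actual <- toupper(unname(tools::md5sum(p$ibd)))
    if (!identical(actual, toupper(declMd5)))
      stop(sprintf("ibd MD5 mismatch: declared %s, actual %s",
                   declMd5, actual))
  }

  groupPrec <- function(groupAcc) {
    grp <- xml2::xml_find_first(doc, sprintf(
      "//%sreferenceableParamGroup[%scvParam/@accession='%s']",
      pfx, pfx, groupAcc))
    if (inherits(grp, "xml_missing"))
      stop("imzML lacks the referenceable param group for ", groupAcc)
    id <- xml2::xml_attr(grp, "id")
    is64 <- !inherits(xml2::xml_find_first(
      grp, sprintf("%scvParam[@accession='MS:1000523']", pfx)),
      "xml_missing")
    is32 <- !inherits(xml2::xml_find_first(
      grp, sprintf("%scvParam[@accession='MS:1000521']", pfx)),
      "xml_missing")
    if (!is64 && !is32)
      stop("unsupported binary precision for group '", id,
           "' (only 32/64-bit float)")
    list(id = id, size = if (is64) 8L else 4L)
  }
  mzGrp <- groupPrec("MS:1000514")
  intGrp <- groupPrec("MS:1000515")

  attrNum <- function(xpath) {
    as.numeric(xml2::xml_attr(xml2::xml_find_all(doc, xpath), "value"))
  }
  posx <- attrNum(sprintf("//%scvParam[@accession='IMS:1000050']", pfx))
  posy <- attrNum(sprintf("//%scvParam[@accession='IMS:1000051']", pfx))
  n <- length(posx)
  if (length(posy) != n)
    stop("inconsistent pixel position metadata (x/y count differ)")
  arrMeta <- function(ref, acc) {
    attrNum(sprintf(
      "//%sbinaryDataArray[%sreferenceableParamGroupRef/@ref='%s']/%scvParam[@accession='%s']",
      pfx, pfx, ref, pfx, acc))
  }
  mzOff <- arrMeta(mzGrp$id, "IMS:1000102")
  mzLen <- arrMeta(mzGrp$id, "IMS:1000103")
  intOff <- arrMeta(intGrp$id, "IMS:1000102")
  intLen <- arrMeta(intGrp$id, "IMS:1000103")
  if (length(mzOff) != n || length(intOff) != n)
    stop("per-spectrum binary array metadata incomplete")
  if (any(c(mzOff + mzLen * mzGrp$size, intOff + intLen * intGrp$size) >
          ibdSize))
    stop("binary array extends beyond the end of the ibd file")

  readArr <- function(off, len, size) {
    seek(con, off)
    readBin(con, "double", n = len, size = size, endian = "little")
  }
  mzList <- vector("list", n)
  intList <- vector("list", n)
  if (isCont && n > 0L) {
    sharedMz <- readArr(mzOff[1], mzLen[1], mzGrp$size)
    for (i in seq_len(n)) mzList[[i]] <- sharedMz
  } else {
    for (i in seq_len(n)) mzList[[i]] <- readArr(mzOff[i], mzLen[i],
                                                 mzGrp$size)
  }
  for (i in seq_len(n)) intList[[i]] <- readArr(intOff[i], intLen[i],
                                                intGrp$size)
  for (i in seq_len(n)) {
    if (length(mzList[[i]]) > 1L && any(diff(mzList[[i]]) <= 0))
      stop(sprintf(
        "pixel %d (x=%d, y=%d): m/z array not strictly ascending; refusing to reorder",
        i, as.integer(posx[i]), as.integer(posy[i])))
  }

  ss <- sprintf("//%sscanSettings", pfx)
  px <- c(as.numeric(.xmlCvValue(doc, pfx, "IMS:1000046", ss)),
          as.numeric(.xmlCvValue(doc, pfx, "IMS:1000047", ss)))
  if (length(px) != 2L || any(is.na(px))) px <- c(400, 400)
  lo <- xml2::xml_find_first(
    doc, sprintf("//%suserParam[@name='lowest observed m/z']", pfx))
  hi <- xml2::xml_find_first(
    doc, sprintf("//%suserParam[@name='highest observed m/z']", pfx))
  rng <- if (!inherits(lo, "xml_missing") && !inherits(hi, "xml_missing")) {
    c(as.numeric(xml2::xml_attr(lo, "value")),
      as.numeric(xml2::xml_attr(hi, "value")))
  } else NULL
  pol <- if (!is.null(.xmlCvValue(doc, pfx, "MS:1000129")))
    "negative" else "positive"

  SpectrumGrid(cbind(x = as.integer(posx), y = as.integer(posy)),
               mzList, intList, pixelSize = px, mzRange = rng,
               polarity = pol,
               metadata = list(source = basename(p$imzml),
                               binary_mode = if (isCont) "continuous"
                                             else "processed"))
}
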