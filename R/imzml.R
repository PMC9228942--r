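# imzML 1.1 reader/writer (continuous and processed mode), with the binary
# ibd companion. Both arrays are stored as uncompressed 64-bit floats; the
# reader also accepts 32-bit floats. Pixel positions are 1-based in the file
# and shifted to the package's 0-based convention on read.

IMS_CONTINUOUS <- "IMS:1000030"
IMS_PROCESSED <- "IMS:1000031"
IMS_UUID <- "IMS:1000080"
IMS_POS_X <- "IMS:1000050"
IMS_POS_Y <- "IMS:1000051"
IMS_EXT_OFFSET <- "IMS:1000102"
IMS_EXT_LENGTH <- "IMS:1000103"
IMS_EXT_ENCODED <- "IMS:1000104"

ibd_path <- function(path) {
  sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
}

#' Read an imzML file
#'
#' Reads an imzML/ibd pair (continuous or processed mode) into an
#' [msi_image]. Class label and patient id are not part of imzML; supply
#' them here or via [read_manifest()] + [apply_manifest()].
#'
#' @param path Path to the `.imzML` XML file; the `.ibd` companion must sit
#'   next to it.
#' @param image_id Identifier for the image; defaults to the file name.
#' @param patient_id,class_label Optional metadata overrides.
#' @param polarity Optional override; otherwise taken from the file (default
#'   `"positive"` when absent).
#' @return An [msi_image].
#' @export
read_imzml <- function(path, image_id = NULL, patient_id = NA_character_,
                       class_label = "unknown", polarity = NULL) {
  if (!file.exists(path)) abort(sprintf("imzML file not found: %s", path))
  ibd <- ibd_path(path)
  if (!file.exists(ibd)) {
    abort(sprintf("missing ibd companion for '%s' (expected '%s')", path, ibd))
  }
  if (is.null(image_id)) image_id <- sub("\\.imzml$", "", basename(path),
                                         ignore.case = TRUE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  acc <- xml2::xml_attr(xml2::xml_find_all(doc, ".//fileContent/cvParam"),
                        "accession")
  continuous <- IMS_CONTINUOUS %in% acc
  if (!continuous && !(IMS_PROCESSED %in% acc)) {
    abort("imzML file declares neither continuous nor processed mode")
  }

  if (is.null(polarity)) {
    pol_acc <- xml2::xml_attr(
      xml2::xml_find_all(doc, ".//spectrum//cvParam"), "accession")
    polarity <- if ("MS:1000129" %in% pol_acc) "negative" else "positive"
  }

  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  n <- length(spectra)
  if (n == 0) abort(sprintf("imzML file '%s' contains no spectra", path))

  cv_value <- function(node, accession) {
    v <- xml2::xml_attr(
      xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']",
                                         accession)), "value")
    as.numeric(v)
  }

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)

  coords <- matrix(0L, n, 2)
  mz_list <- vector("list", n)
  int_list <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    coords[i, 1] <- as.integer(cv_value(sp, IMS_POS_X)) - 1L
    coords[i, 2] <- as.integer(cv_value(sp, IMS_POS_Y)) - 1L
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, ".//referenceableParamGroupRef"), "ref")
      len <- cv_value(arr, IMS_EXT_LENGTH)
      off <- cv_value(arr, IMS_EXT_OFFSET)
      enc <- cv_value(arr, IMS_EXT_ENCODED)
      size <- if (is.finite(enc) && len > 0) enc / len else 8
      seek(con, where = off, origin = "start")
      vals <- readBin(con, "double", n = len, size = size)
      if (identical(ref, "mzArray")) mz_list[[i]] <- vals
      else int_list[[i]] <- vals
    }
    if (is.null(mz_list[[i]]) || is.null(int_list[[i]])) {
      abort(sprintf("spectrum %d: missing m/z or intensity array", i))
    }
    if (length(mz_list[[i]]) > 1 && any(diff(mz_list[[i]]) <= 0)) {
      abort(sprintf(
        "spectrum %d (x=%d, y=%d): m/z axis is not strictly increasing",
        i, coords[i, 1], coords[i, 2]))
    }
  }

  coords <- tibble::tibble(x = coords[, 1], y = coords[, 2])
  if (continuous) {
    mz <- mz_list[[1]]
    intensities <- do.call(rbind, int_list)
    msi_image(intensities, mz, coords, image_id, patient_id,
              class_label, polarity)
  } else {
    msi_image(int_list, mz_list, coords, image_id, patient_id,
              class_label, polarity)
  }
}

#' Write an imzML file
#'
#' Emits a continuous-mode imzML/ibd pair when all pixels share one m/z
#' axis, processed-mode otherwise. `read_imzml(write_imzml(x))` reproduces
#' `x` up to float precision.
#'
#' @param image An [msi_image].
#' @param path Output path ending in `.imzML`; the `.ibd` companion is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(image, path) {
  stopifnot(inherits(image, "msi_image"))
  n <- n_pixels(image)
  if (n == 0) abort("cannot write an image with no pixels")
  ibd <- ibd_path(path)

  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  uuid_str <- paste0(
    "{", substr(paste(format(uuid), collapse = ""), 1, 8), "-",
    paste(format(uuid[5:6]), collapse = ""), "-",
    paste(format(uuid[7:8]), collapse = ""), "-",
    paste(format(uuid[9:10]), collapse = ""), "-",
    paste(format(uuid[11:16]), collapse = ""), "}")

  con <- file(ibd, "wb")
  ok <- FALSE
  on.exit(if (!ok) unlink(c(ibd, path)), add = TRUE)
  writeBin(uuid, con)
  offset <- 16

  # (offset, length) bookkeeping per spectrum
  mz_meta <- matrix(0, n, 2)
  int_meta <- matrix(0, n, 2)
  if (image$continuous) {
    writeBin(as.numeric(image$mz), con, size = 8)
    mz_meta[, 1] <- offset
    mz_meta[, 2] <- length(image$mz)
    offset <- offset + 8 * length(image$mz)
    for (i in seq_len(n)) {
      v <- as.numeric(image$intensities[i, ])
      writeBin(v, con, size = 8)
      int_meta[i, ] <- c(offset, length(v))
      offset <- offset + 8 * length(v)
    }
  } else {
    for (i in seq_len(n)) {
      mzv <- as.numeric(image$mz[[i]])
      writeBin(mzv, con, size = 8)
      mz_meta[i, ] <- c(offset, length(mzv))
      offset <- offset + 8 * length(mzv)
      v <- as.numeric(image$intensities[[i]])
      writeBin(v, con, size = 8)
      int_meta[i, ] <- c(offset, length(v))
      offset <- offset + 8 * length(v)
    }
  }
  close(con)

  mode_param <- if (image$continuous) {
    sprintf('<cvParam cvRef="IMS" accession="%s" name="continuous"/>',
            IMS_CONTINUOUS)
  } else {
    sprintf('<cvParam cvRef="IMS" accession="%s" name="processed"/>',
            IMS_PROCESSED)
  }
  pol_param <- if (image$polarity == "negative") {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  }

  array_block <- function(ref, off, len) {
    paste0(
      '<binaryDataArray encodedLength="0">',
      sprintf('<referenceableParamGroupRef ref="%s"/>', ref),
      sprintf('<cvParam cvRef="IMS" accession="%s" name="external array length" value="%d"/>',
              IMS_EXT_LENGTH, len),
      sprintf('<cvParam cvRef="IMS" accession="%s" name="external offset" value="%.0f"/>',
              IMS_EXT_OFFSET, off),
      sprintf('<cvParam cvRef="IMS" accession="%s" name="external encoded length" value="%d"/>',
              IMS_EXT_ENCODED, 8L * len),
      "<binary/></binaryDataArray>")
  }

  spectra <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="0">',
              i - 1L, i),
      pol_param,
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="%s" name="position x" value="%d"/>',
              IMS_POS_X, image$coords$x[i] + 1L),
      sprintf('<cvParam cvRef="IMS" accession="%s" name="position y" value="%d"/>',
              IMS_POS_Y, image$coords$y[i] + 1L),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      array_block("mzArray", mz_meta[i, 1], as.integer(mz_meta[i, 2])),
      array_block("intensityArray", int_meta[i, 1], as.integer(int_meta[i, 2])),
      "</binaryDataArrayList></spectrum>")
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    mode_param,
    sprintf('<cvParam cvRef="IMS" accession="%s" name="universally unique identifier" value="%s"/>',
            IMS_UUID, uuid_str),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    sprintf('<run id="%s">', gsub("[^A-Za-z0-9_.-]", "_", image$image_id)),
    sprintf('<spectrumList count="%d">', n),
    paste(spectra, collapse = ""),
    "</spectrumList></run></mzML>\n")

  writeLines(xml, path, useBytes = TRUE)
  ok <- TRUE
  invisible(path)
}
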