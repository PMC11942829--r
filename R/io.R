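#' Study input/output
#'
#' Dynamic studies are written as multiframe nuclear-medicine DICOM
#' (explicit VR little endian, unsigned 16-bit counts, one temporal frame
#' per slice) and as compressed array archives; ROI masks as 0/255 PNG
#' images with a JSON sidecar naming each mask's role. The DICOM dialect
#' is deliberately minimal — enough tags for faithful round-trips of
#' counts, frame timing and patient metadata — not a full conformance
#' implementation.
#'
#' @name study_io
NULL

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_NM <- "1.2.840.10008.5.1.4.1.1.20"

pad_even <- function(r) if (length(r) %% 2) c(r, as.raw(0)) else r

dcm_element <- function(group, element, vr, value_raw) {
  hdr <- writeBin(c(as.integer(group), as.integer(element)), raw(),
                  size = 2, endian = "little")
  value_raw <- pad_even(value_raw)
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_str <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(as.character(s)))
}

dcm_us <- function(group, element, v) {
  dcm_element(group, element, "US",
              writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

uint16_to_raw <- function(v) {
  lo <- as.raw(v %% 256L)
  hi <- as.raw(v %/% 256L)
  as.vector(rbind(lo, hi))
}

#' Write a dynamic study as multiframe DICOM
#'
#' Counts are stored as unsigned 16-bit integers (an overflow check
#' rejects counts above 65535); frames are stored in temporal order,
#' row-major within each frame. The frame duration goes to the
#' frame-time tag (milliseconds) and patient age and study id to patient
#' metadata, so [read_dicom_study()] reproduces the study exactly.
#'
#' @param record A `study_record` (from [study_record()]) or a
#'   `dynamic_study`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dicom_study <- function(record, path) {
  study <- if (inherits(record, "dynamic_study")) record else record$study
  fr <- study$frames
  d <- dim(fr)
  if (any(fr < 0) || any(fr != round(fr)))
    stop("counts must be non-negative integers")
  if (max(fr) > 65535)
    stop("count overflow: values exceed unsigned 16-bit range")
  n <- d[1]; H <- d[2]; W <- d[3]

  # deterministic instance UID so identical studies write identical bytes
  sop_uid <- paste0("1.2.826.0.1.3680043.9.7432.",
                    format(sum(as.double(fr)) %% 1e8, scientific = FALSE), ".",
                    sum(utf8ToInt(study$study_id)) %% 99991L)
  px <- integer(n * H * W)
  off <- 0L
  for (i in seq_len(n)) {
    px[off + seq_len(H * W)] <- as.integer(t(fr[i, , ]))  # row-major
    off <- off + H * W
  }

  meta <- c(
    dcm_str(0x0002, 0x0002, "UI", .SOP_NM),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE))
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        writeBin(length(meta), raw(), size = 4,
                                 endian = "little")),
            meta)

  body <- c(
    dcm_str(0x0008, 0x0016, "UI", .SOP_NM),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "NM"),
    dcm_str(0x0010, 0x0020, "LO", study$study_id),
    dcm_str(0x0010, 0x4000, "LT",
            sprintf("age_years=%.6g;provenance=%s", study$patient_age_years,
                    study$provenance)),
    dcm_str(0x0018, 0x1063, "DS", sprintf("%.6g", study$frame_duration_s * 1000)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_str(0x0028, 0x0008, "IS", as.character(n)),
    dcm_us(0x0028, 0x0010, H),
    dcm_us(0x0028, 0x0011, W),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_element(0x7FE0, 0x0010, "OW", uint16_to_raw(px)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_u16 <- function(r, i) {
  as.integer(r[i]) + 256L * as.integer(r[i + 1])
}

read_u32 <- function(r, i) {
  as.integer(r[i]) + 256 * as.integer(r[i + 1]) +
    65536 * as.integer(r[i + 2]) + 16777216 * as.integer(r[i + 3])
}

#' Read a multiframe DICOM study
#'
#' Parses explicit-VR little-endian multiframe files. Frames are ordered
#' by temporal index; stored counts are preserved exactly (if rescale
#' slope/intercept tags are present they are applied and the result
#' re-rounded). A missing frame-time tag falls back to 10 s with a
#' warning.
#'
#' @param path Path to the DICOM file.
#' @return A `study_record`.
#' @export
read_dicom_study <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  r <- readBin(path, raw(), file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("format error: not a DICOM file")
  i <- 133L
  tags <- list()
  long_vr <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (i + 7 <= length(r)) {
    group <- read_u16(r, i); element <- read_u16(r, i + 2)
    vr <- rawToChar(r[(i + 4):(i + 5)])
    if (vr %in% long_vr) {
      if (i + 11 > length(r)) stop("format error: truncated element header")
      len <- read_u32(r, i + 8)
      vs <- i + 12L
    } else {
      len <- read_u16(r, i + 6)
      vs <- i + 8L
    }
    if (vs + len - 1 > length(r))
      stop("format error: truncated file (element value exceeds file size)")
    key <- sprintf("%04X,%04X", group, element)
    tags[[key]] <- list(vr = vr, value = r[seq.int(vs, length.out = len)])
    i <- vs + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  getstr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$value))
  }
  getus <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    read_u16(t$value, 1)
  }
  if (is.null(tags[["7FE0,0010"]]))
    stop("format error: missing pixel data")
  H <- getus("0028,0010"); W <- getus("0028,0011")
  if (is.null(H) || is.null(W))
    stop("format error: missing image dimensions")
  nf <- as.integer(getstr("0028,0008"))
  if (is.na(nf) || nf < 1) nf <- 1L
  pd <- tags[["7FE0,0010"]]$value
  if (length(pd) != 2 * nf * H * W)
    stop("format error: pixel data size does not match frame dimensions")
  v <- as.integer(pd[seq(1, length(pd), 2)]) +
    256L * as.integer(pd[seq(2, length(pd), 2)])
  slope <- getstr("0028,1053"); inter <- getstr("0028,1052")
  if (!is.null(slope) || !is.null(inter)) {
    v <- round(v * ifelse(is.null(slope), 1, as.numeric(slope)) +
                 ifelse(is.null(inter), 0, as.numeric(inter)))
  }
  frames <- array(0L, dim = c(nf, H, W))
  off <- 0L
  for (f in seq_len(nf)) {
    frames[f, , ] <- matrix(v[off + seq_len(H * W)], H, W, byrow = TRUE)
    off <- off + H * W
  }
  ft <- getstr("0018,1063")
  if (is.null(ft)) {
    warning("missing frame-time tag; assuming 10 s per frame")
    dur <- 10
  } else dur <- as.numeric(ft) / 1000
  age <- NA_real_; prov <- "dicom"
  cm <- getstr("0010,4000")
  if (!is.null(cm)) {
    m <- regmatches(cm, regexec("age_years=([0-9.eE+-]+)", cm))[[1]]
    if (length(m) == 2) age <- as.numeric(m[2])
    m <- regmatches(cm, regexec("provenance=([a-z]+)", cm))[[1]]
    if (length(m) == 2) prov <- m[2]
  }
  sid <- getstr("0010,0020")
  study <- list(frames = frames, frame_duration_s = dur,
                patient_age_years = age,
                study_id = if (is.null(sid)) basename(path) else sid,
                provenance = prov, seed = NA_integer_)
  class(study) <- "dynamic_study"
  study_record(study, source_path = path)
}

#' Bundle a study with optional ROIs into a record
#'
#' @param study A `dynamic_study`.
#' @param rois Optional `roi_set`.
#' @param source_path Where the study came from.
#' @return A `study_record`; `protocol_conformant` is `TRUE` for
#'   120-frame 128 x 128 studies and a warning flag otherwise.
#' @export
study_record <- function(study, rois = NULL, source_path = NA_character_) {
  d <- dim(study$frames)
  conform <- (d[1] == 120 && d[2] == 128 && d[3] == 128)
  rec <- list(study = study, rois = rois, source_path = source_path,
              protocol_conformant = conform)
  class(rec) <- "study_record"
  rec
}

#' @export
print.study_record <- function(x, ...) {
  print(x$study)
  cat(sprintf("  protocol conformant: %s; ROIs: %s\n",
              x$protocol_conformant, !is.null(x$rois)))
  invisible(x)
}

#' Write/read a study as a compressed array archive
#'
#' A gzip-compressed archive with keys `frames`, `age`, `duration`,
#' `seed`, `study_id`, `provenance`.
#'
#' @param study A `dynamic_study`.
#' @param path Archive path.
#' @return Invisibly `path` (writer) / a `dynamic_study` (reader).
#' @export
write_study_archive <- function(study, path) {
  saveRDS(list(frames = study$frames, age = study$patient_age_years,
               duration = study$frame_duration_s, seed = study$seed,
               study_id = study$study_id, provenance = study$provenance),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_study_archive
#' @export
read_study_archive <- function(path) {
  z <- readRDS(path)
  study <- list(frames = z$frames, frame_duration_s = z$duration,
                patient_age_years = z$age, study_id = z$study_id,
                provenance = z$provenance, seed = z$seed)
  class(study) <- "dynamic_study"
  study
}

#' Write ROI masks as PNG files with a JSON sidecar
#'
#' Each mask becomes a 0/255 grayscale PNG; the sidecar maps each mask
#' role to its file name.
#'
#' @param rois An `roi_set`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_roi_masks <- function(rois, dir, prefix = "roi") {
  validate_roi_set(rois)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- list()
  for (nm in c("left_kidney", "right_kidney", "background")) {
    fn <- paste0(prefix, "_", nm, ".png")
    png::writePNG(rois[[nm]] * 1, file.path(dir, fn))
    sidecar[[nm]] <- fn
  }
  sp <- file.path(dir, paste0(prefix, "_masks.json"))
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE)
  invisible(sp)
}

#' Read ROI masks written by [write_roi_masks()]
#'
#' Masks are binarized at half intensity (>= 128 of 255); roles come
#' from the sidecar. Empty or overlapping kidney masks are rejected.
#'
#' @param sidecar_path Path to the JSON sidecar.
#' @return An `roi_set`.
#' @export
read_roi_masks <- function(sidecar_path) {
  if (!file.exists(sidecar_path)) stop("sidecar not found: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  dir <- dirname(sidecar_path)
  out <- list()
  for (nm in c("left_kidney", "right_kidney", "background")) {
    if (is.null(sc[[nm]]))
      stop("format error: sidecar missing role '", nm, "'")
    img <- png::readPNG(file.path(dir, sc[[nm]]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    out[[nm]] <- img >= 128 / 255
  }
  dims <- lapply(out, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("format error: mask shapes differ")
  class(out) <- "roi_set"
  validate_roi_set(out)
  out
}
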