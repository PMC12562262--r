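binary_labels <- c("normal", "abnormal")
three_labels <- c("present", "absent", "unknown")

#' Load and validate a dataset manifest CSV
#'
#' The manifest schema is `record_id, subject_id, path, label` — the same
#' for synthetic and real corpora, so every loader feeds the identical
#' downstream pipeline. Validation errors name the offending row.
#'
#' @param path Manifest CSV path.
#' @param class_mode `"binary"` (normal/abnormal) or `"three_class"`
#'   (present/absent/unknown).
#' @param check_paths Verify that every referenced file exists.
#' @return A tibble manifest with attribute `class_mode`.
#' @export
load_manifest <- function(path, class_mode = c("binary", "three_class"),
                          check_paths = TRUE) {
  class_mode <- match.arg(class_mode)
  man <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("record_id", "subject_id", "path", "label")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  allowed <- if (class_mode == "binary") binary_labels else three_labels
  bad <- which(!man$label %in% allowed)
  if (length(bad)) {
    stop("unknown label \"", man$label[bad[1]], "\" in row ", bad[1],
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  dup <- which(duplicated(man$record_id))
  if (length(dup)) {
    stop("duplicate record_id \"", man$record_id[dup[1]], "\" in row ", dup[1],
         call. = FALSE)
  }
  if (check_paths) {
    # relative paths resolve against the manifest's directory
    abs <- ifelse(file.exists(man$path), man$path,
                  file.path(dirname(path), man$path))
    gone <- which(!file.exists(abs))
    if (length(gone)) {
      stop("file not found for row ", gone[1], ": ", man$path[gone[1]],
           call. = FALSE)
    }
    man$path <- abs
  }
  attr(man, "class_mode") <- class_mode
  man
}

#' Load a PhysioNet 2016 style directory
#'
#' Expects the challenge layout: a directory of WAV files plus a
#' `REFERENCE.csv` with record name and -1/1 label (-1 normal, 1 abnormal).
#' The corpus carries no patient identifiers, so the record name doubles as
#' the subject id (one recording per nominal subject) — a documented
#' limitation of subject-wise splitting on this corpus.
#'
#' @param root Directory containing WAVs and `REFERENCE.csv`.
#' @return A binary-mode manifest tibble.
#' @export
load_physionet2016 <- function(root) {
  ref_path <- file.path(root, "REFERENCE.csv")
  if (!file.exists(ref_path)) {
    stop("missing REFERENCE.csv under ", root, call. = FALSE)
  }
  ref <- utils::read.csv(ref_path, header = FALSE,
                         col.names = c("record", "code"),
                         stringsAsFactors = FALSE)
  paths <- file.path(root, paste0(ref$record, ".wav"))
  gone <- which(!file.exists(paths))
  if (length(gone)) {
    stop("WAV missing for record \"", ref$record[gone[1]], "\": ",
         paths[gone[1]], call. = FALSE)
  }
  man <- tibble::tibble(
    record_id = ref$record,
    subject_id = ref$record,     # record name is the subject proxy
    path = paths,
    label = ifelse(ref$code == 1, "abnormal", "normal")
  )
  attr(man, "class_mode") <- "binary"
  man
}

#' Load a PhysioNet 2022 style directory
#'
#' Expects the challenge layout: one `<patient>.txt` metadata file per
#' patient (header line `<patient> <n_locations> <rate>`, one line per
#' recorded auscultation location naming its WAV, and annotation lines such
#' as `#Murmur: Present`), plus the per-location WAVs. The murmur label of
#' the patient is applied to all of that patient's recordings, and the
#' patient id is the subject id, so splitting is truly subject-wise.
#'
#' @param root Directory with patient metadata and WAVs.
#' @return A three-class manifest tibble.
#' @export
load_physionet2022 <- function(root) {
  meta_files <- list.files(root, pattern = "^[^.]+\\.txt$", full.names = TRUE)
  if (!length(meta_files)) {
    stop("no patient metadata (*.txt) under ", root, call. = FALSE)
  }
  rows <- purrr::map(meta_files, function(mf) {
    lines <- readLines(mf, warn = FALSE)
    pid <- strsplit(trimws(lines[1]), "\\s+")[[1]][1]
    murmur <- sub("^#Murmur:\\s*", "", grep("^#Murmur:", lines, value = TRUE))
    if (!length(murmur)) {
      stop("no #Murmur annotation in ", mf, call. = FALSE)
    }
    label <- tolower(murmur[1])
    if (!label %in% three_labels) {
      stop("unrecognized murmur label \"", murmur[1], "\" in ", mf,
           call. = FALSE)
    }
    wavs <- regmatches(lines, regexpr("\\S+\\.wav", lines))
    wavs <- unique(unlist(wavs))
    if (!length(wavs)) stop("no recordings listed in ", mf, call. = FALSE)
    paths <- file.path(root, wavs)
    gone <- which(!file.exists(paths))
    if (length(gone)) {
      stop("WAV listed in ", basename(mf), " not found: ", wavs[gone[1]],
           call. = FALSE)
    }
    tibble::tibble(record_id = sub("\\.wav$", "", wavs),
                   subject_id = pid, path = paths, label = label)
  })
  man <- dplyr::bind_rows(rows)
  attr(man, "class_mode") <- "three_class"
  man
}
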