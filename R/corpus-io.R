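#' Write a corpus to delimited text and MGF
#'
#' Writes `files.csv` (per-run metadata), `peptides.csv` (evidence table)
#' and `spectra.mgf` (standard MGF with BEGIN IONS / TITLE / PEPMASS /
#' CHARGE blocks). Numeric fields are written with fixed precision so that
#' write -> read -> write is byte-stable.
#'
#' @param corpus an [LcmsCorpus-class].
#' @param directory output directory, created if missing.
#' @return invisibly, the paths written.
#' @seealso [readCorpus()]
#' @export
writeCorpus <- function(corpus, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- corpusFiles(corpus)
  peptides <- corpusPeptides(corpus)
  fmt <- function(x, digits) {
    out <- sprintf(paste0("%.", digits, "f"), x)
    out[is.na(x)] <- NA
    out
  }
  files$gradient_length <- fmt(files$gradient_length, 4)
  files$mz_lower <- fmt(files$mz_lower, 4)
  files$mz_upper <- fmt(files$mz_upper, 4)
  peptides$score <- fmt(peptides$score, 4)
  peptides$rt <- fmt(peptides$rt, 6)
  peptides$rt_normalized <- fmt(peptides$rt_normalized, 6)
  peptides$precursor_mz <- fmt(peptides$precursor_mz, 6)
  fFiles <- file.path(directory, "files.csv")
  fPep <- file.path(directory, "peptides.csv")
  fMgf <- file.path(directory, "spectra.mgf")
  utils::write.csv(files, fFiles, row.names = FALSE, na = "")
  utils::write.csv(peptides, fPep, row.names = FALSE, na = "")
  writeMgf(corpusSpectra(corpus), fMgf)
  invisible(c(files = fFiles, peptides = fPep, spectra = fMgf))
}

#' Read a corpus written by [writeCorpus()]
#'
#' @param directory directory containing `files.csv`, `peptides.csv` and
#'   `spectra.mgf`.
#' @return an [LcmsCorpus-class] (with `config = NULL`).
#' @export
readCorpus <- function(directory) {
  fFiles <- file.path(directory, "files.csv")
  fPep <- file.path(directory, "peptides.csv")
  for (f in c(fFiles, fPep)) {
    if (!file.exists(f)) stop("missing corpus file: ", f)
  }
  cls <- c(file_id = "character", project_id = "character",
           species = "character", sequence = "character")
  files <- utils::read.csv(fFiles, stringsAsFactors = FALSE,
                           colClasses = cls[c("file_id", "project_id",
                                              "species")])
  peptides <- utils::read.csv(fPep, stringsAsFactors = FALSE,
                              colClasses = cls[c("sequence", "file_id",
                                                 "project_id")])
  if (!nrow(peptides)) {
    peptides <- data.frame(sequence = character(), score = numeric(),
                           rt = numeric(), rt_normalized = numeric(),
                           precursor_mz = numeric(), charge = integer(),
                           file_id = character(), project_id = character(),
                           stringsAsFactors = FALSE)
  }
  if (!nrow(files)) {
    files <- data.frame(file_id = character(), project_id = character(),
                        gradient_length = numeric(), mz_lower = numeric(),
                        mz_upper = numeric(), species = character(),
                        stringsAsFactors = FALSE)
  }
  if ("rt_normalized" %in% names(peptides)) {
    peptides$rt_normalized <- as.numeric(peptides$rt_normalized)
  }
  fMgf <- file.path(directory, "spectra.mgf")
  spectra <- if (file.exists(fMgf)) readMgf(fMgf) else list()
  new("LcmsCorpus", files = files, peptides = peptides, spectra = spectra,
      config = NULL)
}

#' Write spectra as Mascot Generic Format
#'
#' @param spectra list of [SpectrumPeakSet-class] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    lines <- c(
      "BEGIN IONS",
      sprintf("TITLE=%s FILE=%s ENERGY=%.4f", sp@spectrumId, sp@fileId,
              sp@energy),
      sprintf("PEPMASS=%.6f", sp@precursorMz),
      sprintf("CHARGE=%d+", sp@charge),
      sprintf("%.6f %.6f", sp@mz, sp@intensity),
      "END IONS")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a Mascot Generic Format peak list
#'
#' A minimal strict MGF reader: expects BEGIN IONS / END IONS blocks with
#' TITLE, PEPMASS and CHARGE headers and `m/z intensity` peak lines. Parse
#' errors name the offending line.
#'
#' @param path the MGF file.
#' @return list of [SpectrumPeakSet-class] objects.
#' @export
readMgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1; next }
    if (line != "BEGIN IONS") {
      stop(sprintf("MGF parse error at line %d: expected BEGIN IONS, got '%s'",
                   i, line))
    }
    title <- fileId <- NA_character_
    energy <- pepmass <- NA_real_
    charge <- NA_integer_
    mz <- numeric(0)
    intensity <- numeric(0)
    i <- i + 1
    repeat {
      if (i > n) stop(sprintf("MGF parse error: unterminated block at line %d", i))
      line <- trimws(lines[i])
      if (line == "END IONS") { i <- i + 1; break }
      if (grepl("^TITLE=", line)) {
        body <- sub("^TITLE=", "", line)
        parts <- strsplit(body, " ")[[1]]
        title <- parts[1]
        fm <- grep("^FILE=", parts, value = TRUE)
        if (length(fm)) fileId <- sub("^FILE=", "", fm[1])
        em <- grep("^ENERGY=", parts, value = TRUE)
        if (length(em)) energy <- as.numeric(sub("^ENERGY=", "", em[1]))
      } else if (grepl("^PEPMASS=", line)) {
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line), " ")[[1]][1])
      } else if (grepl("^CHARGE=", line)) {
        charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", line)))
      } else if (grepl("^[0-9]", line)) {
        parts <- strsplit(line, "[ \t]+")[[1]]
        if (length(parts) < 2 || anyNA(suppressWarnings(as.numeric(parts[1:2])))) {
          stop(sprintf("MGF parse error at line %d: bad peak line '%s'",
                       i, line))
        }
        mz <- c(mz, as.numeric(parts[1]))
        intensity <- c(intensity, as.numeric(parts[2]))
      } else if (!grepl("=", line)) {
        stop(sprintf("MGF parse error at line %d: unrecognized line '%s'",
                     i, line))
      }
      i <- i + 1
    }
    spectra[[length(spectra) + 1]] <- new(
      "SpectrumPeakSet", spectrumId = title, fileId = fileId, mz = mz,
      intensity = intensity, precursorMz = pepmass, charge = charge,
      energy = if (is.na(energy)) 0 else energy)
  }
  spectra
}

#' Read / write a corpus configuration as YAML
#'
#' `corpus.yaml` mirrors every [CorpusConfig-class] field, so simulation
#' settings can be stored alongside the generated corpus.
#'
#' @param path the YAML file.
#' @return for `readCorpusConfig`, a [CorpusConfig-class].
#' @export
readCorpusConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gradientModes)) {
    y$gradientModes <- data.frame(minutes = as.numeric(y$gradientModes$minutes),
                                  weight = as.numeric(y$gradientModes$weight))
  }
  if (!is.null(y$retentionScale)) y$retentionScale <- unlist(y$retentionScale)
  do.call(corpusConfig, y)
}

#' @rdname readCorpusConfig
#' @param config a [CorpusConfig-class].
#' @export
writeCorpusConfig <- function(config, path) {
  slots <- slotNames(config)
  y <- lapply(slots, function(s) {
    v <- slot(config, s)
    if (is.data.frame(v)) as.list(v) else v
  })
  names(y) <- slots
  y$retentionScale <- as.list(config@retentionScale)
  yaml::write_yaml(y, path)
  invisible(path)
}
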