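#' Construct a stratified dataset specification
#'
#' @param minScore minimal identification score, boundary inclusive.
#' @param maxPeptides peptide-count cap (seeded uniform downsample).
#' @param gradientStratum `"none"`, `"short"` (gradient <= 60 min) or
#'   `"long"` (gradient >= 100 min).
#' @param mzStratum `"none"`, `"lower"` (precursor m/z < 360) or `"upper"`
#'   (precursor m/z > 1300).
#' @param species optional species label.
#' @param excludeProjects project ids to drop.
#' @param seed downsampling seed.
#' @return a [DatasetSpec-class].
#' @export
datasetSpec <- function(minScore = 100, maxPeptides = Inf,
                        gradientStratum = "none", mzStratum = "none",
                        species = NA_character_,
                        excludeProjects = character(), seed = 1L) {
  new("DatasetSpec", minScore = minScore, maxPeptides = maxPeptides,
      gradientStratum = gradientStratum, mzStratum = mzStratum,
      species = species, excludeProjects = excludeProjects,
      seed = as.integer(seed))
}

#' Read a dataset specification from YAML
#'
#' @param path `dataset.yaml` mirroring the [datasetSpec()] arguments.
#' @return a [DatasetSpec-class].
#' @export
readDatasetSpec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(datasetSpec, y)
}

#' Filter peptides into a stratified dataset
#'
#' Applies, in order: project exclusions, the score threshold (inclusive),
#' the gradient stratum (evaluated against per-file metadata), the m/z
#' stratum (evaluated against the record's precursor), the species
#' restriction, and finally a seeded uniform downsample to `maxPeptides`.
#' The output row order is deterministic given the seed. Filtering an
#' already-filtered set is the identity.
#'
#' @param records peptide record data.frame.
#' @param spec a [DatasetSpec-class].
#' @param files per-run metadata; required for gradient or species strata.
#' @return the filtered records.
#' @export
filterPeptides <- function(records, spec, files = NULL) {
  validObject(spec)
  keep <- rep(TRUE, nrow(records))
  keep <- keep & !(records$project_id %in% spec@excludeProjects)
  keep <- keep & records$score >= spec@minScore
  if (spec@gradientStratum != "none" || !is.na(spec@species)) {
    if (is.null(files)) {
      stop("gradient or species strata require per-file metadata")
    }
    m <- match(records$file_id, files$file_id)
    if (anyNA(m[keep])) {
      stop("records reference files missing from metadata: ",
           paste(utils::head(unique(records$file_id[keep][is.na(m[keep])]), 3),
                 collapse = ", "))
    }
    if (spec@gradientStratum == "short") {
      keep <- keep & files$gradient_length[m] <= 60
    } else if (spec@gradientStratum == "long") {
      keep <- keep & files$gradient_length[m] >= 100
    }
    if (!is.na(spec@species)) {
      keep <- keep & files$species[m] == spec@species
    }
  }
  if (spec@mzStratum == "lower") {
    keep <- keep & records$precursor_mz < 360
  } else if (spec@mzStratum == "upper") {
    keep <- keep & records$precursor_mz > 1300
  }
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  if (nrow(out) > spec@maxPeptides) {
    idx <- withr::with_seed(spec@seed,
      sort(sample.int(nrow(out), spec@maxPeptides)))
    out <- out[idx, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Remove modified peptides
#'
#' Retains only sequences over the 20-residue canonical alphabet; anything
#' with modification annotation (brackets, lowercase, symbols) is dropped.
#'
#' @param records peptide record data.frame.
#' @return records with canonical sequences only.
#' @export
removeModified <- function(records) {
  pat <- sprintf("^[%s]+$", paste(RESIDUES, collapse = ""))
  out <- records[grepl(pat, records$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Effective-gradient (iRT-like) normalization
#'
#' Per raw file, retention times are rescaled linearly so the first
#' identified peptide maps to exactly 0 and the last to exactly 1:
#' `rt_normalized = (rt - min rt) / (max rt - min rt)`. Raw retention times
#' are retained. Files with fewer than 2 distinct retention times cannot be
#' normalized; their records are dropped with a warning naming the files
#' (never silently zeroed) and returned in the `rejected` attribute.
#'
#' @param records peptide record data.frame with `rt` and `file_id`.
#' @return records with `rt_normalized` filled; attributes
#'   `rejectedFiles` (character) and `rejected` (the dropped records).
#' @examples
#' rec <- data.frame(file_id = "f", rt = c(5, 10, 15))
#' normalizeEffectiveGradient(rec)$rt_normalized
#' @export
normalizeEffectiveGradient <- function(records) {
  grp <- split(seq_len(nrow(records)), records$file_id)
  rejected <- character(0)
  rtn <- rep(NA_real_, nrow(records))
  for (fid in names(grp)) {
    idx <- grp[[fid]]
    rt <- records$rt[idx]
    lo <- min(rt)
    hi <- max(rt)
    if (hi - lo <= 0) {
      rejected <- c(rejected, fid)
    } else {
      rtn[idx] <- (rt - lo) / (hi - lo)
    }
  }
  if (length(rejected)) {
    warning("rejected ", length(rejected),
            " file(s) with < 2 distinct retention times: ",
            paste(utils::head(rejected, 10), collapse = ", "))
  }
  keep <- !(records$file_id %in% rejected)
  out <- records[keep, , drop = FALSE]
  out$rt_normalized <- rtn[keep]
  rownames(out) <- NULL
  attr(out, "rejectedFiles") <- rejected
  attr(out, "rejected") <- records[!keep, , drop = FALSE]
  out
}

#' Hold-out split by whole projects or whole raw files
#'
#' Units (projects or files) are shuffled by the seed and greedily assigned
#' to the test set whenever adding the unit moves the test peptide share
#' closer to `fraction`; units that would move it further away are skipped.
#' Whole-unit splitting cannot hit the fraction exactly; this rule is
#' deterministic and auditable. At least one unit always lands in test.
#'
#' @param records peptide record data.frame.
#' @param level `"project"` or `"file"`.
#' @param fraction target test peptide share.
#' @param seed shuffle seed.
#' @return list with `test` and `remainder` data.frames and `testUnits`.
#' @export
holdoutSplit <- function(records, level = c("project", "file"),
                         fraction = 0.10, seed = 1L) {
  level <- match.arg(level)
  unitCol <- if (level == "project") "project_id" else "file_id"
  units <- unique(records[[unitCol]])
  if (length(units) < 2) {
    stop("only one ", level, " available; split at the other level instead")
  }
  sizes <- table(records[[unitCol]])[units]
  total <- nrow(records)
  order <- withr::with_seed(as.integer(seed), sample(units))
  share <- 0
  chosen <- character(0)
  for (u in order) {
    cand <- share + sizes[[u]] / total
    if (abs(cand - fraction) <= abs(share - fraction)) {
      chosen <- c(chosen, u)
      share <- cand
    }
  }
  if (!length(chosen)) {
    dev <- abs(sizes / total - fraction)
    chosen <- names(dev)[which.min(dev)]
  }
  if (length(chosen) == length(units)) chosen <- chosen[-length(chosen)]
  inTest <- records[[unitCol]] %in% chosen
  list(test = records[inTest, , drop = FALSE],
       remainder = records[!inTest, , drop = FALSE],
       testUnits = chosen)
}

#' Train/validation split by peptide sequence
#'
#' Unique sequences are shuffled by the seed and assigned 80:20 (by
#' sequence count); all records of a sequence travel together, so no
#' sequence ever occurs in both partitions.
#'
#' @param records peptide record data.frame.
#' @param ratio train share of unique sequences.
#' @param seed shuffle seed.
#' @return list with `train` and `validation` data.frames.
#' @export
trainValSplitBySequence <- function(records, ratio = 0.80, seed = 1L) {
  seqs <- unique(records$sequence)
  if (length(seqs) < 2) stop("need at least 2 unique sequences to split")
  shuffled <- withr::with_seed(as.integer(seed), sample(seqs))
  nTrain <- max(1, min(length(seqs) - 1, round(ratio * length(seqs))))
  trainSeqs <- shuffled[seq_len(nTrain)]
  inTrain <- records$sequence %in% trainSeqs
  list(train = records[inTrain, , drop = FALSE],
       validation = records[!inTrain, , drop = FALSE])
}

#' Build a full train/validation/test bundle
#'
#' Convenience wrapper reproducing the study's split protocol: normalize
#' retention times to the effective gradient (unless already normalized),
#' hold out ~10% of peptides as whole projects (or whole files for
#' single-project data), then split the remainder 80:20 by peptide
#' sequence.
#'
#' @param records peptide record data.frame.
#' @param holdoutLevel `"auto"` (project when >1 project), `"project"` or
#'   `"file"`.
#' @param fraction hold-out peptide share.
#' @param ratio train share of the remainder's unique sequences.
#' @param seed split seed.
#' @param normalize normalize first (default TRUE when `rt_normalized` is
#'   absent or all NA).
#' @return a [SplitBundle-class].
#' @export
buildSplitBundle <- function(records, holdoutLevel = "auto",
                             fraction = 0.10, ratio = 0.80, seed = 1L,
                             normalize = NULL) {
  if (is.null(normalize)) {
    normalize <- !("rt_normalized" %in% names(records)) ||
      all(is.na(records$rt_normalized))
  }
  rejected <- records[0, , drop = FALSE]
  if (normalize) {
    records <- normalizeEffectiveGradient(records)
    rejected <- attr(records, "rejected")
  }
  if (identical(holdoutLevel, "auto")) {
    holdoutLevel <- if (length(unique(records$project_id)) > 1) "project"
                    else "file"
  }
  ho <- holdoutSplit(records, holdoutLevel, fraction, seed)
  tv <- trainValSplitBySequence(ho$remainder, ratio, seed)
  new("SplitBundle", train = tv$train, validation = tv$validation,
      test = ho$test, holdoutLevel = holdoutLevel, seed = as.integer(seed),
      rejected = rejected)
}

#' Write a split bundle as CSV plus a manifest
#'
#' Emits `train.csv`, `val.csv`, `test.csv` (all with `rt_normalized`) and
#' `split_manifest.json` recording the seed, hold-out level, test units and
#' rejected files.
#'
#' @param bundle a [SplitBundle-class].
#' @param directory output directory.
#' @return invisibly, the manifest path.
#' @export
writeSplitBundle <- function(bundle, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trainSet(bundle), file.path(directory, "train.csv"),
                   row.names = FALSE)
  utils::write.csv(validationSet(bundle), file.path(directory, "val.csv"),
                   row.names = FALSE)
  utils::write.csv(testSet(bundle), file.path(directory, "test.csv"),
                   row.names = FALSE)
  unitCol <- if (bundle@holdoutLevel == "project") "project_id" else "file_id"
  manifest <- list(
    seed = bundle@seed, holdout_level = bundle@holdoutLevel,
    test_units = unique(bundle@test[[unitCol]]),
    n_train = nrow(bundle@train), n_validation = nrow(bundle@validation),
    n_test = nrow(bundle@test),
    rejected_files = unique(bundle@rejected$file_id))
  path <- file.path(directory, "split_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
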