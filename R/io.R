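# Readers and writers for the formats the pipeline touches (FASTA, TSV,
# JSON), the data-hygiene filters, and report serialisation.

.parseHeader <- function(h) {
  parts <- strsplit(h, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3L) return(NULL)
  list(taxon = parts[1], side = toupper(parts[2]), sample = parts[3])
}

.readFasta <- function(path) {
  tryCatch(Biostrings::readDNAStringSet(path),
           error = function(e) stop("cannot parse FASTA '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Load taxon-pair alignments from FASTA
#'
#' Each file holds one gene for one taxon.  Headers following the
#' \code{taxonID|side|sampleID} convention (side \code{E} or \code{W})
#' are parsed directly; otherwise a \code{sideMap} (named vector, sample
#' id to side) must cover every sample.  Multi-gene taxa (several rows of
#' \code{files} sharing a taxon) are concatenated in the declared gene
#' order; samples missing a gene are padded with N over that gene's
#' range.  All sequences of a gene must share one aligned length.
#'
#' @param files character vector of FASTA paths (single-gene taxa, taxon
#'   taken from the headers) or a data.frame with columns \code{path},
#'   \code{taxon} and optionally \code{gene} (declared order).
#' @param sideMap optional named vector, sample id to \code{"E"}/\code{"W"},
#'   used when headers do not follow the pipe convention.
#' @return named list of \linkS4class{TaxonPairAlignment}.
#' @export
loadDataset <- function(files, sideMap = NULL) {
  if (is.character(files))
    files <- data.frame(path = files, taxon = NA_character_,
                        gene = NA_character_)
  if (!"gene" %in% names(files)) files$gene <- NA_character_
  recs <- lapply(seq_len(nrow(files)), function(i) {
    seqs <- .readFasta(files$path[i])
    info <- lapply(names(seqs), .parseHeader)
    taxon <- files$taxon[i]
    samples <- character(length(seqs)); side <- character(length(seqs))
    for (j in seq_along(seqs)) {
      if (!is.null(info[[j]])) {
        if (is.na(taxon)) taxon <- info[[j]]$taxon
        samples[j] <- info[[j]]$sample
        side[j] <- info[[j]]$side
      } else {
        samples[j] <- names(seqs)[j]
        side[j] <- NA_character_
      }
    }
    if (!is.null(sideMap)) {
      mapped <- toupper(unname(sideMap[samples]))
      side <- ifelse(is.na(side), mapped, side)
    }
    if (anyNA(side) || !all(side %in% c("E", "W")))
      stop("sample(s) without side assignment in '", files$path[i], "': ",
           paste(samples[is.na(side) | !(side %in% c("E", "W"))],
                 collapse = ", "))
    if (is.na(taxon)) stop("cannot determine taxon for '", files$path[i],
                           "'; provide a 'taxon' column")
    w <- Biostrings::width(seqs)
    if (length(unique(w)) != 1L)
      stop("length mismatch within gene '", files$gene[i], "' of taxon '",
           taxon, "'")
    list(taxon = taxon, gene = files$gene[i], samples = samples,
         side = side, seqs = as.character(seqs), L = w[1])
  })
  taxa <- unique(vapply(recs, `[[`, character(1), "taxon"))
  out <- lapply(taxa, function(tx) {
    gs <- Filter(function(r) r$taxon == tx, recs)
    allSamples <- unique(unlist(lapply(gs, `[[`, "samples")))
    sideOf <- setNames(rep(NA_character_, length(allSamples)), allSamples)
    for (g in gs) sideOf[g$samples] <- g$side
    cat_ <- vapply(allSamples, function(sm) {
      paste(vapply(gs, function(g) {
        k <- match(sm, g$samples)
        if (is.na(k)) strrep("N", g$L) else g$seqs[k]
      }, character(1)), collapse = "")
    }, character(1))
    starts <- cumsum(c(1, head(vapply(gs, `[[`, numeric(1), "L"), -1)))
    gr <- data.frame(gene = vapply(gs, `[[`, character(1), "gene"),
                     start = as.integer(starts),
                     end = as.integer(starts +
                                      vapply(gs, `[[`, numeric(1), "L") - 1))
    e <- cat_[sideOf == "E"]; w <- cat_[sideOf == "W"]
    es <- Biostrings::DNAStringSet(e); ws <- Biostrings::DNAStringSet(w)
    names(es) <- sprintf("%s|E|%s", tx, names(e))
    names(ws) <- sprintf("%s|W|%s", tx, names(w))
    taxonPairAlignment(tx, east = es, west = ws, geneRanges = gr)
  })
  names(out) <- taxa
  out
}

.missingFrac <- function(seq) {
  ch <- strsplit(toupper(as.character(seq)), "")[[1]]
  mean(!(ch %in% c("A", "C", "G", "T")))
}

#' Apply the missing-data and minimum-sampling filters
#'
#' Drops any sequence whose fraction of missing characters (anything
#' other than A/C/G/T, so N, gaps and ambiguity codes all count)
#' strictly exceeds \code{threshold}; a sequence at exactly the
#' threshold is retained.  Taxa left with fewer than \code{minPerSide}
#' sequences on either side are excluded entirely.
#'
#' @param data list of \linkS4class{TaxonPairAlignment}.
#' @param threshold missing-data fraction above which a sample is
#'   dropped (default 0.5).
#' @param minPerSide minimum samples per side after filtering
#'   (default 3).
#' @return list with \code{data} (the surviving alignments) and
#'   \code{report} (data.frame: taxon, sample, side, fracMissing,
#'   action).
#' @export
filterMissing <- function(data, threshold = 0.5, minPerSide = 3L) {
  if (is(data, "TaxonPairAlignment")) data <- list(data)
  report <- data.frame(taxon = character(), sample = character(),
                       side = character(), fracMissing = numeric(),
                       action = character())
  kept <- list()
  for (x in data) {
    sets <- list(E = x@east, W = x@west)
    newSets <- list()
    for (sd_ in c("E", "W")) {
      ss <- sets[[sd_]]
      fr <- vapply(seq_along(ss), function(i) .missingFrac(ss[i]),
                   numeric(1))
      drop <- fr > threshold
      if (any(drop))
        report <- rbind(report, data.frame(
          taxon = x@taxon, sample = names(ss)[drop], side = sd_,
          fracMissing = fr[drop], action = "sample_dropped"))
      newSets[[sd_]] <- ss[!drop]
    }
    if (length(newSets$E) < minPerSide || length(newSets$W) < minPerSide) {
      report <- rbind(report, data.frame(
        taxon = x@taxon, sample = NA_character_, side = NA_character_,
        fracMissing = NA_real_, action = "taxon_excluded"))
    } else {
      kept[[x@taxon]] <- taxonPairAlignment(x@taxon, newSets$E, newSets$W,
                                            x@geneRanges)
    }
  }
  list(data = kept, report = report)
}

#' Write a taxon-pair alignment as FASTA
#'
#' Headers follow the \code{taxonID|side|sampleID} convention.
#'
#' @param x a \linkS4class{TaxonPairAlignment}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTaxonPairFasta <- function(x, path) {
  seqs <- c(x@east, x@west)
  lines <- character(0)
  for (i in seq_along(seqs))
    lines <- c(lines, paste0(">", names(seqs)[i]), as.character(seqs[[i]]))
  writeLines(lines, path)
  invisible(path)
}

#' Serialise an analysis report
#'
#' Writes a machine-readable JSON (full numeric precision, including the
#' seed and configuration for reproducibility) plus TSV tables: the
#' Bayes-factor table (threshold, BF01, label), the pulse-grouping table,
#' and the per-taxon summary statistics.  Identical inputs produce
#' byte-identical files.
#'
#' @param result an \linkS4class{HABCResult}.
#' @param dir output directory (created if needed).
#' @param extra optional named list merged into the JSON (e.g. a GLM
#'   ranking).
#' @return named vector of file paths, invisibly.
#' @export
writeReport <- function(result, dir, extra = NULL) {
  stopifnot(is(result, "HABCResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- posteriorSummary(result@posterior)
  payload <- list(
    seed = result@seed,
    config = result@config,
    prior = result@prior,
    thetaRef = result@thetaRef,
    psiFreq = as.list(result@posterior@psiFreq),
    psiMode = psiMode(result@posterior),
    omega = as.list(ps["omega", ]),
    eTau = as.list(ps["eTau", ]),
    bayesFactors = result@bf,
    pulses = result@pulses,
    perTaxon = result@perTaxon)
  if (!is.null(extra)) payload <- c(payload, extra)
  paths <- c(json = file.path(dir, "report.json"),
             bf = file.path(dir, "bayes_factors.tsv"),
             pulses = file.path(dir, "pulses.tsv"),
             stats = file.path(dir, "per_taxon_stats.tsv"))
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  wtsv <- function(df, p) utils::write.table(df, p, sep = "\t",
                                             quote = FALSE,
                                             row.names = FALSE)
  wtsv(result@bf, paths["bf"])
  wtsv(result@pulses, paths["pulses"])
  wtsv(result@perTaxon, paths["stats"])
  invisible(paths)
}
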