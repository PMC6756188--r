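#' Local-ancestry window calls
#'
#' Window calls are represented as a \code{GRanges} (1-based inclusive
#' spans), one range per (haplotype, window), with metadata columns
#' \code{sample_id}, \code{side}, and one posterior column per ancestry
#' label; the ancestry labels are recorded in
#' \code{metadata(x)$ancestries}.  This is the package's documented TSV
#' dialect standing in for RFMix-class per-window output: any converter
#' that produces (span, haplotype, posterior vector) rows can feed it.
#'
#' @param df \code{data.frame} with columns \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{sample_id}, \code{side}, then one numeric column
#'   per ancestry label.
#' @return a \code{GRanges} of validated window calls, grouped per
#'   haplotype and ordered by start within each group.
#' @export
windowCalls <- function(df) {
    fixed <- c("chrom", "start_bp", "end_bp", "sample_id", "side")
    checkColumns(df, fixed, "window calls")
    anc <- setdiff(colnames(df), fixed)
    if (length(anc) < 2) stopf("window calls need at least two ancestry columns")
    post <- as.matrix(df[, anc, drop = FALSE])
    if (any(post < 0 | post > 1))
        stopf("posterior outside [0, 1] at row %d",
              which(rowSums(post < 0 | post > 1) > 0)[1])
    bad <- which(abs(rowSums(post) - 1) > 1e-6)
    if (length(bad))
        stopf("posteriors do not sum to 1 at row %d (sum = %.6f)",
              bad[1], rowSums(post)[bad[1]])
    if (any(df$end_bp < df$start_bp))
        stopf("end_bp < start_bp at row %d", which(df$end_bp < df$start_bp)[1])
    ord <- order(df$sample_id, df$side, df$chrom, df$start_bp)
    df <- df[ord, ]; post <- post[ord, , drop = FALSE]
    gr <- GRanges(as.character(df$chrom),
                  IRanges(df$start_bp, df$end_bp),
                  sample_id = as.character(df$sample_id),
                  side = as.integer(df$side))
    for (a in anc) S4Vectors::mcols(gr)[[a]] <- unname(post[, a])
    ## rows are sorted by (sample, side, chrom, start): an overlap can only
    ## involve consecutive rows of the same haplotype/chromosome group
    key <- paste(df$sample_id, df$side, df$chrom)
    n <- nrow(df)
    if (n > 1) {
        same <- key[-1] == key[-n]
        ov <- same & df$start_bp[-1] <= df$end_bp[-n]
        if (any(ov))
            stopf("overlapping windows for haplotype %s", key[which(ov)[1]])
    }
    S4Vectors::metadata(gr)$ancestries <- anc
    gr
}

#' Read window calls from TSV
#'
#' Tab-separated with header: \code{chrom}, \code{start_bp}, \code{end_bp},
#' \code{sample_id}, \code{side}, then one posterior column per ancestry
#' label.  Coordinates are 1-based inclusive.
#'
#' @param path TSV file.
#' @return a \code{GRanges} of window calls (see [windowCalls()]).
#' @export
readWindowCalls <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    windowCalls(df)
}

#' Write window calls to TSV
#'
#' @param calls window calls \code{GRanges} from [windowCalls()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWindowCalls <- function(calls, path) {
    anc <- S4Vectors::metadata(calls)$ancestries
    df <- data.frame(chrom = as.character(seqnames(calls)),
                     start_bp = start(calls), end_bp = end(calls),
                     sample_id = calls$sample_id, side = calls$side,
                     check.names = FALSE)
    for (a in anc) df[[a]] <- S4Vectors::mcols(calls)[[a]]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Filter windows by posterior and merge runs into fragments
#'
#' A window is kept iff its posterior for the target ancestry is strictly
#' greater than \code{minPosterior} (default 0.8).  Within each haplotype
#' (and chromosome), maximal runs of kept windows that are consecutive in
#' the window sequence are concatenated into a single fragment spanning the
#' first window's start to the last window's end.  Two kept windows
#' separated by a discarded window are never merged; adjacency is in the
#' window sequence, not in base pairs.
#'
#' @param calls window calls \code{GRanges} (see [windowCalls()]).
#' @param target target ancestry label (must be one of the posterior
#'   columns).
#' @param minPosterior posterior threshold, strict inequality; default 0.8.
#' @return fragments as a \code{GRanges} with metadata columns
#'   \code{fragment_id}, \code{source_sample}, \code{source_side},
#'   \code{ancestry}, \code{n_windows}.
#' @export
filterAndMerge <- function(calls, target, minPosterior = 0.8) {
    anc <- S4Vectors::metadata(calls)$ancestries
    if (is.null(anc)) anc <- setdiff(colnames(S4Vectors::mcols(calls)),
                                     c("sample_id", "side"))
    if (!target %in% anc)
        stopf("unknown target ancestry '%s' (have: %s)", target,
              paste(anc, collapse = ", "))
    post <- S4Vectors::mcols(calls)[[target]]
    keep <- post > minPosterior
    chrom <- as.character(seqnames(calls))
    ord <- order(calls$sample_id, calls$side, chrom, start(calls))
    key <- paste(calls$sample_id, calls$side, chrom, sep = "\r")[ord]
    kp <- keep[ord]
    if (!any(kp)) return(emptyFragments(target))
    ## a new run starts at a kept window whose predecessor (within the same
    ## haplotype/chromosome group) is absent or not kept
    n <- length(kp)
    newrun <- kp & c(TRUE, !kp[-n] | key[-1] != key[-n])
    runid <- cumsum(newrun)
    ki <- which(kp)
    io <- ord[ki]
    rid <- runid[ki]
    first <- !duplicated(rid)
    last <- !duplicated(rid, fromLast = TRUE)
    df <- data.frame(
        chrom = chrom[io[first]],
        start_bp = start(calls)[io[first]],
        end_bp = end(calls)[io[last]],
        source_sample = calls$sample_id[io[first]],
        source_side = calls$side[io[first]],
        n_windows = as.integer(tabulate(rid)[unique(rid)]))
    df$fragment_id <- sprintf("frag%06d_%s_%d", seq_len(nrow(df)),
                              df$source_sample, df$source_side)
    df$ancestry <- target
    fragmentsFromDf(df)
}

emptyFragments <- function(target = NA_character_) {
    GRanges(character(), IRanges(integer(), integer()),
            fragment_id = character(), source_sample = character(),
            source_side = integer(), ancestry = character(),
            n_windows = integer())
}

fragmentsFromDf <- function(df) {
    GRanges(df$chrom, IRanges(df$start_bp, df$end_bp),
            fragment_id = df$fragment_id,
            source_sample = df$source_sample,
            source_side = as.integer(df$source_side),
            ancestry = df$ancestry,
            n_windows = as.integer(df$n_windows))
}

#' Fragment TSV round trip
#'
#' BED-like tab-separated dialect, 1-based inclusive, with header columns
#' \code{chrom}, \code{start_bp}, \code{end_bp}, \code{fragment_id},
#' \code{source_sample}, \code{source_side}, \code{ancestry},
#' \code{n_windows}.
#'
#' @param fragments fragments \code{GRanges} (see [filterAndMerge()]).
#' @param path file path.
#' @return \code{writeFragments}: \code{path}, invisibly;
#'   \code{readFragments}: the fragments \code{GRanges}.
#' @export
writeFragments <- function(fragments, path) {
    df <- data.frame(chrom = as.character(seqnames(fragments)),
                     start_bp = start(fragments), end_bp = end(fragments),
                     fragment_id = fragments$fragment_id,
                     source_sample = fragments$source_sample,
                     source_side = fragments$source_side,
                     ancestry = fragments$ancestry,
                     n_windows = fragments$n_windows)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFragments
#' @export
readFragments <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    checkColumns(df, c("chrom", "start_bp", "end_bp", "fragment_id",
                       "source_sample", "source_side", "ancestry",
                       "n_windows"), "fragments file")
    bad <- which(df$end_bp < df$start_bp)
    if (length(bad))
        stopf("end_bp < start_bp at line %d of %s", bad[1] + 1L, path)
    if (anyDuplicated(df$fragment_id))
        stopf("duplicated fragment_id in %s", path)
    fragmentsFromDf(df)
}
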