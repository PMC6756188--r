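#' Construct a GeneticMap from anchor points
#'
#' @param anchors \code{data.frame} with columns \code{chrom}, \code{pos_bp},
#'   \code{cm}; at least two anchors per chromosome, strictly increasing in
#'   \code{pos_bp} and non-decreasing in \code{cm}.
#' @return a \linkS4class{GeneticMap}.
#' @export
#' @examples
#' m <- GeneticMap(data.frame(chrom = "1", pos_bp = c(1, 1e6 + 1),
#'                            cm = c(0, 1)))
#' interpolateCm(m, "1", 500001)
GeneticMap <- function(anchors) {
    checkColumns(anchors, c("chrom", "pos_bp", "cm"), "genetic map")
    anchors <- data.frame(chrom = as.character(anchors$chrom),
                          pos_bp = as.numeric(anchors$pos_bp),
                          cm = as.numeric(anchors$cm))
    anchors <- anchors[order(anchors$chrom, anchors$pos_bp), ]
    rownames(anchors) <- NULL
    new("GeneticMap", anchors = anchors)
}

#' Uniform-rate genetic map
#'
#' Convenience constructor: a two-anchor map in which \code{totalCm}
#' centimorgans are spread uniformly over \code{[1, lengthBp]}.
#'
#' @param chrom chromosome label.
#' @param lengthBp chromosome length in base pairs.
#' @param totalCm genetic length in centimorgans.
#' @return a \linkS4class{GeneticMap}.
#' @export
uniformGeneticMap <- function(chrom, lengthBp, totalCm) {
    GeneticMap(data.frame(chrom = chrom, pos_bp = c(1, lengthBp),
                          cm = c(0, totalCm)))
}

#' Read a genetic map file
#'
#' Whitespace-separated columns \code{chrom}, \code{pos_bp}, \code{cm}
#' (header optional, extra columns ignored).
#'
#' @param path map file.
#' @return a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path) {
    first <- readLines(path, n = 1)
    hasHeader <- grepl("chrom", first, ignore.case = TRUE)
    df <- utils::read.table(path, header = hasHeader,
                            stringsAsFactors = FALSE)
    if (!hasHeader) colnames(df)[1:3] <- c("chrom", "pos_bp", "cm")
    GeneticMap(df[, c("chrom", "pos_bp", "cm")])
}

#' Write a genetic map file
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneticMap <- function(map, path) {
    utils::write.table(map@anchors, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Interpolate genetic position
#'
#' Linear interpolation between map anchors; positions before the first or
#' after the last anchor clamp to the boundary centimorgan value.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom chromosome label.
#' @param posBp base-pair positions (vectorised).
#' @return centimorgan positions.
#' @export
interpolateCm <- function(map, chrom, posBp) {
    a <- map@anchors[map@anchors$chrom == as.character(chrom), ]
    if (nrow(a) < 2) stopf("no map anchors for chromosome %s", chrom)
    stats::approx(a$pos_bp, a$cm, xout = posBp, rule = 2, ties = "ordered")$y
}

#' Invert a genetic map (cM to bp)
#'
#' Maps centimorgan positions back to base pairs by linear interpolation;
#' values outside the anchored cm range clamp to the boundary position.
#' Flat map segments (zero recombination) resolve to their left edge.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom chromosome label.
#' @param cm centimorgan positions (vectorised).
#' @return base-pair positions (numeric).
#' @export
interpolateBp <- function(map, chrom, cm) {
    a <- map@anchors[map@anchors$chrom == as.character(chrom), ]
    if (nrow(a) < 2) stopf("no map anchors for chromosome %s", chrom)
    stats::approx(a$cm, a$pos_bp, xout = cm, rule = 2, ties = min)$y
}

setMethod("show", "GeneticMap", function(object) {
    a <- object@anchors
    for (ch in unique(a$chrom)) {
        sub <- a[a$chrom == ch, ]
        cat(sprintf("GeneticMap %s: %d anchors, %.0f-%.0f bp, %.3f-%.3f cM\n",
                    ch, nrow(sub), min(sub$pos_bp), max(sub$pos_bp),
                    min(sub$cm), max(sub$cm)))
    }
})
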