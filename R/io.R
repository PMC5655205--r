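## Readers and writers for expression tables and network files.

.splitTable <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(NULL)
    sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
    lapply(strsplit(lines, sep, fixed = TRUE), trimws)
}

#' Read a time-series expression matrix
#'
#' Reads a tab- or comma-separated numeric table with one header line of
#' labels. With `layout = "genes_in_rows"` the first field of every data
#' row is the gene id and the header labels the time points; with
#' `layout = "genes_in_columns"` the header carries the gene ids and each
#' row is one time point. Either way the result has genes in rows, in order
#' of first appearance, with the column (time) order preserved.
#'
#' @param path file path.
#' @param layout `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @return numeric genes x time matrix with gene ids as rownames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(1:6, 2, 3, dimnames = list(c("G1", "G2"), NULL)), tf)
#' readExpression(tf)
#' @export
readExpression <- function(path,
                           layout = c("genes_in_rows", "genes_in_columns")) {
    layout <- match.arg(layout)
    cells <- .splitTable(path)
    if (is.null(cells) || length(cells) < 2L)
        stop("expression file needs a header line and at least one data row")
    header <- cells[[1L]]
    body <- cells[-1L]
    nf <- unique(lengths(body))
    if (length(nf) != 1L)
        stop("ragged expression table: rows have differing field counts")
    if (length(header) == nf - 1L) header <- c("", header)
    if (length(header) != nf)
        stop("header length does not match the data rows")
    rowIds <- vapply(body, `[[`, character(1), 1L)
    vals <- matrix(NA_real_, length(body), nf - 1L)
    for (r in seq_along(body)) {
        v <- suppressWarnings(as.numeric(body[[r]][-1L]))
        bad <- which(is.na(v))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                         body[[r]][bad[1L] + 1L], rowIds[r],
                         header[bad[1L] + 1L]))
        vals[r, ] <- v
    }
    if (layout == "genes_in_rows") {
        ids <- rowIds
        mat <- vals
        colnames(mat) <- header[-1L]
    } else {
        ids <- header[-1L]
        mat <- t(vals)
        colnames(mat) <- rowIds
    }
    if (anyDuplicated(ids))
        stop(sprintf("duplicate gene id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    rownames(mat) <- ids
    mat
}

#' Write an expression matrix
#'
#' Tab-separated, genes in rows, one header line of time labels.
#'
#' @param expr numeric genes x time matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeExpression <- function(expr, path) {
    expr <- .asExprMatrix(expr)
    if (is.null(colnames(expr)))
        colnames(expr) <- paste0("t", seq_len(ncol(expr)))
    lines <- c(paste(c("gene", colnames(expr)), collapse = "\t"),
               vapply(seq_len(nrow(expr)), function(i)
                   paste(c(rownames(expr)[i],
                           sprintf("%.10g", expr[i, ])), collapse = "\t"),
                   character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Read a network file
#'
#' `fmt = "edge_list"`: whitespace-separated columns regulator, target and
#' optionally delay and score (a `regulator target ...` header line is
#' skipped); SIF files written by [writeNetwork()] (interaction strings
#' `regulates_d<delay>`) are detected and parsed too.
#' `fmt = "dream_gold"`: three columns regulator, target, label in
#' {0, 1}; only label-1 rows become edges, and absent pairs count as label
#' 0. Self-loop rows are dropped with a warning. Gene order is the order of
#' first appearance unless a reference `geneIds` vector is supplied, in
#' which case unknown ids raise an error.
#'
#' @param path file path.
#' @param fmt `"edge_list"` or `"dream_gold"`.
#' @param geneIds optional reference gene universe.
#' @return a directed [Network-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("G1 G2 1", "G2 G3 0"), tf)
#' readNetwork(tf, fmt = "dream_gold")
#' @export
readNetwork <- function(path, fmt = c("edge_list", "dream_gold"),
                        geneIds = NULL) {
    fmt <- match.arg(fmt)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- lapply(strsplit(trimws(lines), "[\t ,]+"), trimws)
    if (length(fields) > 0L && identical(tolower(fields[[1L]][1:2]),
                                         c("regulator", "target")))
        fields <- fields[-1L]
    if (length(fields) == 0L) {
        return(makeNetwork(if (is.null(geneIds)) character(0) else geneIds,
                           directed = TRUE))
    }
    if (any(lengths(fields) < if (fmt == "dream_gold") 3L else 2L))
        stop("network file row with too few columns")
    ## SIF lines ("regulator regulates_d<delay> target") are recognised
    ## inside edge_list so that both writeNetwork formats round-trip
    sif <- fmt == "edge_list" && all(lengths(fields) >= 3L) &&
        all(grepl("^regulates_d[0-9]+$",
                  vapply(fields, `[[`, character(1), 2L)))
    if (sif) {
        fields <- lapply(fields, function(f)
            c(f[1L], f[3L], sub("^regulates_d", "", f[2L])))
    }
    reg <- vapply(fields, `[[`, character(1), 1L)
    tgt <- vapply(fields, `[[`, character(1), 2L)
    delay <- rep(NA_integer_, length(reg))
    score <- rep(NA_real_, length(reg))
    if (fmt == "dream_gold") {
        lab <- vapply(fields, `[[`, character(1), 3L)
        if (!all(lab %in% c("0", "1")))
            stop("dream_gold labels must be 0 or 1")
        keep <- lab == "1"
    } else {
        keep <- rep(TRUE, length(reg))
        has3 <- lengths(fields) >= 3L
        delay[has3] <- as.integer(vapply(fields[has3], `[[`,
                                         character(1), 3L))
        has4 <- lengths(fields) >= 4L
        score[has4] <- as.numeric(vapply(fields[has4], `[[`,
                                         character(1), 4L))
    }
    seen <- unique(c(rbind(reg, tgt)))
    if (is.null(geneIds)) geneIds <- seen
    else if (length(bad <- setdiff(seen, geneIds)))
        stop(sprintf("unknown gene id(s): %s", paste(bad, collapse = ", ")))
    loops <- reg == tgt
    if (any(loops & keep)) {
        warning(sprintf("dropped %d self-loop row(s)", sum(loops & keep)))
        keep <- keep & !loops
    }
    dup <- duplicated(paste(reg, tgt, sep = "\r")) & keep
    if (any(dup)) {
        warning(sprintf("dropped %d duplicate edge row(s)", sum(dup)))
        keep <- keep & !dup
    }
    makeNetwork(geneIds, reg[keep], tgt[keep], delay = delay[keep],
                score = score[keep], directed = TRUE)
}

#' Write a network to disk
#'
#' `fmt = "tsv"` writes a four-column table `regulator target delay score`
#' (header included; header-only for an empty network). `fmt = "sif"`
#' writes Cytoscape simple-interaction lines
#' `regulator regulates_d<delay> target`.
#' `readNetwork(writeNetwork(x))` reproduces the edge set and delay entries
#' exactly.
#'
#' @param net a [TimeDelayedGRN-class] or [Network-class].
#' @param path output file path.
#' @param fmt `"tsv"` (default) or `"sif"`.
#' @return the path, invisibly.
#' @examples
#' net <- makeNetwork(c("G7", "G8"), "G7", "G8", delay = 2L, score = 0.9)
#' tf <- tempfile(fileext = ".tsv")
#' writeNetwork(net, tf)
#' readLines(tf)
#' @export
writeNetwork <- function(net, path, fmt = c("tsv", "sif")) {
    fmt <- match.arg(fmt)
    e <- networkEdges(net)
    fmtNum <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))
    if (fmt == "tsv") {
        lines <- c("regulator\ttarget\tdelay\tscore",
                   if (nrow(e) > 0L)
                       paste(e$regulator, e$target,
                             ifelse(is.na(e$delay), "NA", e$delay),
                             fmtNum(e$score), sep = "\t"))
    } else {
        lines <- if (nrow(e) > 0L)
            paste(e$regulator,
                  sprintf("regulates_d%s",
                          ifelse(is.na(e$delay), "0", e$delay)),
                  e$target, sep = "\t")
        else character(0)
    }
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(err) FALSE)
    if (!ok) stop(sprintf("cannot write network file '%s'", path))
    invisible(path)
}
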