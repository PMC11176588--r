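#' Construct a PathwayCollection
#'
#' @param sets named list of character vectors of gene symbols (upper-cased
#'   on construction, duplicates removed).
#' @param descriptions optional named character of pathway descriptions.
#' @param categories optional named character of pathway category labels.
#' @return A [PathwayCollection-class].
#' @export
PathwayCollection <- function(sets, descriptions = NULL, categories = NULL) {
    sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("", length(sets)), names(sets))
    if (is.null(categories)) categories <- stats::setNames(character(), character())
    pc <- methods::new("PathwayCollection", sets = sets,
                       descriptions = descriptions, categories = categories)
    methods::validObject(pc)
    pc
}

#' Read gene sets in GMT format
#'
#' One pathway per line: id, description, then one or more genes, all
#' tab-separated (the MSigDB distribution format). Gene symbols are
#' upper-cased and duplicates within a set removed.
#'
#' @param path path to a GMT file.
#' @return A [PathwayCollection-class].
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        warnf("empty GMT file '%s'", path)
        return(PathwayCollection(stats::setNames(list(), character())))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(fields, length, 1L) < 3)
    if (length(short))
        stopf("GMT line %d has fewer than 3 fields", short[1])
    ids <- vapply(fields, `[`, "", 1L)
    if (anyDuplicated(ids)) stopf("duplicate pathway id in GMT: %s",
                                  ids[duplicated(ids)][1])
    PathwayCollection(
        sets = stats::setNames(lapply(fields, function(f) f[-(1:2)]), ids),
        descriptions = stats::setNames(vapply(fields, `[`, "", 2L), ids))
}

#' Filter pathways against an expression gene universe
#'
#' Applies the pathway selection rules in order: (a) intersect every gene set
#' with the measured gene universe, (b) drop pathways with fewer than
#' `minGenes` remaining genes, (c) drop pathways whose category is excluded,
#' then (d) drop pathways that share at least two genes with no other
#' retained pathway. Rule (d) is a retention filter applied once, not
#' iterated to a fixpoint.
#'
#' @param pc a [PathwayCollection-class].
#' @param universe character vector of measured genes.
#' @param minGenes minimum surviving set size (default 5).
#' @param excludedCategories category labels to drop (e.g. human disease and
#'   drug development collections); default none.
#' @param minOverlap overlap (genes) required with at least one other
#'   retained pathway (default 2); set to 0 to disable rule (d).
#' @return A filtered [PathwayCollection-class] (possibly empty, with a
#'   warning).
#' @export
filterPathways <- function(pc, universe, minGenes = 5,
                           excludedCategories = character(), minOverlap = 2) {
    if (!length(universe)) stopf("gene universe is empty")
    universe <- toupper(universe)
    sets <- lapply(pc@sets, intersect, universe)
    keep <- vapply(sets, length, 1L) >= minGenes
    if (length(excludedCategories) && length(pc@categories)) {
        cat <- pc@categories[names(sets)]
        keep <- keep & !(ifelse(is.na(cat), "", cat) %in% excludedCategories)
    }
    sets <- sets[keep]
    if (minOverlap > 0 && length(sets) > 0) {
        ids <- names(sets)
        hasPartner <- vapply(seq_along(sets), function(i) {
            any(vapply(seq_along(sets)[-i], function(j)
                length(intersect(sets[[i]], sets[[j]])) >= minOverlap, TRUE))
        }, TRUE)
        sets <- sets[hasPartner]
    }
    if (!length(sets)) warnf("no pathways survive filtering")
    desc <- as.character(pc@descriptions[names(sets)])
    desc[is.na(desc)] <- ""
    cats <- pc@categories[intersect(names(pc@categories), names(sets))]
    methods::new("PathwayCollection", sets = sets,
                 descriptions = stats::setNames(desc, names(sets)),
                 categories = cats)
}
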