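# Pathway-collection interchange format: typed interaction records grouped in
# pathways, read/written as JSON (canonical) or flat TSV.

INTERACTION_TYPES <- c("directed", "complex_participation", "catalysis",
                       "inhibition", "conversion", "undirected")
DIRECTED_TYPES <- c("directed", "catalysis", "inhibition", "conversion")
PARTICIPANT_KINDS <- c("gene_product", "metabolite", "complex")
SOURCE_DBS <- c("wikipathways", "reactome", "synthetic")

#' Construct a pathway collection
#'
#' A pathway collection holds a set of pathway models together with their
#' interaction records. Each interaction record belongs to one pathway, has a
#' type from a six-value vocabulary, and lists one or more role-tagged
#' participants (gene products, metabolites, or complexes) identified by
#' namespaced identifiers such as `"ensembl:ENSG..."` or `"chebi:CHEBI:..."`.
#'
#' Internally a collection stores three data frames: `pathways`
#' (pathway_id, title, source_db), `interactions` (pathway_id, local_id,
#' type; one row per interaction record), and `participants` (pathway_id,
#' local_id, participant_id, kind, role; one row per participant of a
#' record).
#'
#' Directed interaction types (`directed`, `catalysis`, `inhibition`,
#' `conversion`) must have at least one `source`- and one `target`-role
#' participant; undirected types (`complex_participation`, `undirected`) may
#' only use the role `participant`.
#'
#' @param pathways data frame with columns `pathway_id`, `title`,
#'   `source_db` (one of `"wikipathways"`, `"reactome"`, `"synthetic"`).
#' @param interactions data frame with columns `pathway_id`, `local_id`,
#'   `type`.
#' @param participants data frame with columns `pathway_id`, `local_id`,
#'   `participant_id`, `kind`, `role`.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(pathways, interactions, participants) {
  pathways <- as.data.frame(pathways, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  obj <- structure(list(pathways = pathways, interactions = interactions,
                        participants = participants),
                   class = "pathway_collection")
  validate_collection(obj)
  obj
}

#' Validate a pathway collection
#'
#' Checks all structural invariants of the interchange format: unique pathway
#' ids, known interaction types and participant kinds, namespaced participant
#' identifiers, every interaction attached to a declared pathway, at least one
#' participant per record, and role/type compatibility (source/target only in
#' directed types, and both present there).
#'
#' @param collection a `pathway_collection`.
#' @return The collection, invisibly; errors on the first violation found.
#' @export
validate_collection <- function(collection) {
  pw <- collection$pathways
  ia <- collection$interactions
  pp <- collection$participants
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("collection %s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(pw, c("pathway_id", "title", "source_db"), "pathways")
  need(ia, c("pathway_id", "local_id", "type"), "interactions")
  need(pp, c("pathway_id", "local_id", "participant_id", "kind", "role"),
       "participants")

  if (anyDuplicated(pw$pathway_id))
    stop("validation error: duplicate pathway_id: ",
         paste(unique(pw$pathway_id[duplicated(pw$pathway_id)]),
               collapse = ", "), call. = FALSE)
  bad_db <- setdiff(unique(pw$source_db), SOURCE_DBS)
  if (length(bad_db))
    stop("validation error: unknown source_db: ",
         paste(bad_db, collapse = ", "), call. = FALSE)

  if (nrow(ia)) {
    bad_type <- setdiff(unique(ia$type), INTERACTION_TYPES)
    if (length(bad_type))
      stop("validation error: unknown interaction_type: ",
           paste(bad_type, collapse = ", "), call. = FALSE)
    orphan <- setdiff(unique(ia$pathway_id), pw$pathway_id)
    if (length(orphan))
      stop("validation error: interaction references undeclared pathway_id: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    rec <- paste(ia$pathway_id, ia$local_id, sep = "\r")
    if (anyDuplicated(rec))
      stop("validation error: duplicate (pathway_id, local_id): ",
           paste(unique(rec[duplicated(rec)]), collapse = "; "),
           call. = FALSE)
    prec <- paste(pp$pathway_id, pp$local_id, sep = "\r")
    orphan_p <- setdiff(unique(prec), rec)
    if (length(orphan_p))
      stop("validation error: participant row for unknown interaction record",
           call. = FALSE)
    empty <- setdiff(rec, unique(prec))
    if (length(empty))
      stop("validation error: interaction record with no participants: ",
           paste(empty, collapse = "; "), call. = FALSE)
  } else if (nrow(pp)) {
    stop("validation error: participant rows without interaction records",
         call. = FALSE)
  }

  if (nrow(pp)) {
    if (any(!nzchar(pp$participant_id)))
      stop("validation error: empty participant entity_id", call. = FALSE)
    ok_ns <- grepl("^[^:]+:.+$", pp$participant_id)
    if (any(!ok_ns))
      stop("validation error: entity_id lacks a namespace prefix: ",
           paste(utils::head(unique(pp$participant_id[!ok_ns]), 5),
                 collapse = ", "), call. = FALSE)
    bad_kind <- setdiff(unique(pp$kind), PARTICIPANT_KINDS)
    if (length(bad_kind))
      stop("validation error: unknown participant kind: ",
           paste(bad_kind, collapse = ", "), call. = FALSE)
    bad_role <- setdiff(unique(pp$role), c("source", "target", "participant"))
    if (length(bad_role))
      stop("validation error: unknown participant role: ",
           paste(bad_role, collapse = ", "), call. = FALSE)

    type_of <- stats::setNames(ia$type, paste(ia$pathway_id, ia$local_id,
                                              sep = "\r"))
    ptype <- type_of[paste(pp$pathway_id, pp$local_id, sep = "\r")]
    undirected <- !(ptype %in% DIRECTED_TYPES)
    if (any(undirected & pp$role != "participant"))
      stop("validation error: role \"source\"/\"target\" used inside an ",
           "undirected interaction type", call. = FALSE)
    dir_rec <- unique(names(ptype)[!undirected])
    if (length(dir_rec)) {
      key <- paste(pp$pathway_id, pp$local_id, sep = "\r")
      has_src <- unique(key[pp$role == "source"])
      has_tgt <- unique(key[pp$role == "target"])
      missing_end <- setdiff(dir_rec, intersect(has_src, has_tgt))
      if (length(missing_end))
        stop("validation error: directed-type interaction lacks a source or ",
             "target participant: ", paste(utils::head(missing_end, 5),
                                           collapse = "; "), call. = FALSE)
    }
  }
  invisible(collection)
}

#' Read a pathway collection from an interchange file
#'
#' @param path file to read.
#' @param format `"json"` (canonical dialect) or `"tsv"` (flat
#'   one-row-per-participant form). Guessed from the file extension when
#'   missing.
#' @return A validated [pathway_collection()].
#' @export
read_collection <- function(path, format = c("json", "tsv")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- if (missing(format))
    guess_format(path) else match.arg(format)
  if (format == "json") read_collection_json(path) else
    read_collection_tsv(path)
}

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv"
  else stop("cannot guess interchange format from extension: ", path,
            call. = FALSE)
}

read_collection_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("parse error in ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  if (!is.list(doc) || is.null(doc$pathways))
    stop("parse error in ", path, ": missing \"pathways\" member",
         call. = FALSE)
  chr1 <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop(sprintf("parse error in %s: record %s lacks \"%s\"", path, where,
                   field), call. = FALSE)
    as.character(x[[field]])
  }
  pw <- do.call(rbind, lapply(seq_along(doc$pathways), function(i) {
    p <- doc$pathways[[i]]
    data.frame(pathway_id = chr1(p, "id", i),
               title = if (is.null(p$title)) "" else as.character(p$title),
               source_db = chr1(p, "source_db", i),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pw))
    pw <- data.frame(pathway_id = character(), title = character(),
                     source_db = character(), stringsAsFactors = FALSE)
  ints <- doc$interactions
  ia_rows <- list(); pp_rows <- list()
  for (i in seq_along(ints)) {
    rec <- ints[[i]]
    pid <- chr1(rec, "pathway", i)
    lid <- chr1(rec, "local_id", i)
    typ <- chr1(rec, "type", i)
    ia_rows[[i]] <- data.frame(pathway_id = pid, local_id = lid, type = typ,
                               stringsAsFactors = FALSE)
    parts <- rec$participants
    if (length(parts))
      pp_rows[[i]] <- data.frame(
        pathway_id = pid, local_id = lid,
        participant_id = vapply(parts, function(q) chr1(q, "id", i), ""),
        kind = vapply(parts, function(q) chr1(q, "kind", i), ""),
        role = vapply(parts, function(q) chr1(q, "role", i), ""),
        stringsAsFactors = FALSE)
  }
  ia <- if (length(ia_rows)) do.call(rbind, ia_rows) else
    data.frame(pathway_id = character(), local_id = character(),
               type = character(), stringsAsFactors = FALSE)
  pp <- if (length(pp_rows)) do.call(rbind, pp_rows) else
    data.frame(pathway_id = character(), local_id = character(),
               participant_id = character(), kind = character(),
               role = character(), stringsAsFactors = FALSE)
  pathway_collection(pw, ia, pp)
}

read_collection_tsv <- function(path) {
  lines <- readLines(path)
  pw_lines <- grep("^#pathway\t", lines, value = TRUE)
  pw <- if (length(pw_lines)) {
    fields <- strsplit(sub("^#pathway\t", "", pw_lines), "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 3)
    if (length(bad))
      stop("parse error in ", path, ": malformed #pathway header line ",
           bad[1], call. = FALSE)
    data.frame(pathway_id = vapply(fields, `[`, "", 1),
               title = vapply(fields, `[`, "", 2),
               source_db = vapply(fields, `[`, "", 3),
               stringsAsFactors = FALSE)
  } else data.frame(pathway_id = character(), title = character(),
                    source_db = character(), stringsAsFactors = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  expected <- "pathway_id\tinteraction_local_id\tinteraction_type\tparticipant_id\tparticipant_kind\trole"
  if (length(body)) {
    if (body[1] != expected)
      stop("parse error in ", path, ": unexpected TSV header", call. = FALSE)
    body <- body[-1]
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6)
  if (length(bad))
    stop("parse error in ", path, ": row ", bad[1],
         " does not have 6 columns", call. = FALSE)
  col <- function(i) vapply(fields, `[`, "", i)
  pp <- data.frame(pathway_id = col(1), local_id = col(2),
                   participant_id = col(4), kind = col(5), role = col(6),
                   stringsAsFactors = FALSE)
  ia_all <- data.frame(pathway_id = col(1), local_id = col(2), type = col(3),
                       stringsAsFactors = FALSE)
  ia <- unique(ia_all)
  rec <- paste(ia$pathway_id, ia$local_id, sep = "\r")
  if (anyDuplicated(rec))
    stop("parse error in ", path,
         ": conflicting interaction_type for one record", call. = FALSE)
  pathway_collection(pw, ia, pp)
}

#' Write a pathway collection to an interchange file
#'
#' The emitted file reads back (with [read_collection()]) to a collection
#' equal to the input up to row ordering, in either dialect. The TSV dialect
#' stores pathway metadata in `#pathway` header comment lines above the
#' 6-column participant table.
#'
#' @param collection a validated `pathway_collection`.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @export
write_collection <- function(collection, path, format = c("json", "tsv")) {
  validate_collection(collection)
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  pw <- collection$pathways
  ia <- collection$interactions
  pp <- collection$participants
  if (format == "json") {
    prec <- paste(pp$pathway_id, pp$local_id, sep = "\r")
    psplit <- split(seq_len(nrow(pp)), prec)
    ints <- lapply(seq_len(nrow(ia)), function(i) {
      idx <- psplit[[paste(ia$pathway_id[i], ia$local_id[i], sep = "\r")]]
      list(pathway = ia$pathway_id[i], local_id = ia$local_id[i],
           type = ia$type[i],
           participants = lapply(idx, function(j)
             list(id = pp$participant_id[j], kind = pp$kind[j],
                  role = pp$role[j])))
    })
    doc <- list(
      pathways = lapply(seq_len(nrow(pw)), function(i)
        list(id = pw$pathway_id[i], title = pw$title[i],
             source_db = pw$source_db[i])),
      interactions = ints)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    type_of <- stats::setNames(ia$type,
                               paste(ia$pathway_id, ia$local_id, sep = "\r"))
    hdr <- sprintf("#pathway\t%s\t%s\t%s", pw$pathway_id, pw$title,
                   pw$source_db)
    colhdr <- "pathway_id\tinteraction_local_id\tinteraction_type\tparticipant_id\tparticipant_kind\trole"
    rows <- if (nrow(pp)) sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s", pp$pathway_id, pp$local_id,
      unname(type_of[paste(pp$pathway_id, pp$local_id, sep = "\r")]),
      pp$participant_id, pp$kind, pp$role) else character()
    # records with participants cover all records (validated invariant)
    writeLines(c(hdr, colhdr, rows), path)
  }
  invisible(NULL)
}

#' Order-insensitive equality of two pathway collections
#'
#' @param a,b `pathway_collection` objects.
#' @return TRUE when both collections contain the same pathways, interaction
#'   records and participant rows, regardless of row order.
#' @export
collections_equal <- function(a, b) {
  canon <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  isTRUE(all.equal(canon(a$pathways), canon(b$pathways))) &&
    isTRUE(all.equal(canon(a$interactions), canon(b$interactions))) &&
    isTRUE(all.equal(canon(a$participants), canon(b$participants)))
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathway(s), %d interaction record(s), %d participant row(s)\n",
              nrow(x$pathways), nrow(x$interactions), nrow(x$participants)))
  if (nrow(x$interactions)) {
    census <- sort(table(x$interactions$type), decreasing = TRUE)
    cat("  record types:",
        paste(sprintf("%s=%d", names(census), census), collapse = ", "), "\n")
  }
  invisible(x)
}
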