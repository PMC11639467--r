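#' Parse a MeSH heading field value into a descriptor
#'
#' An `MH` field value carries a descriptor name, optionally followed by
#' `/`-separated subheadings (qualifiers); a leading `*` on the name or on a
#' qualifier marks the heading as a major topic of the record
#' (e.g. `"Kidney Failure, Chronic/*veterinary"`).
#'
#' @param raw character vector of `MH` field values.
#' @return A data frame with one row per input: `name` (canonical descriptor:
#'   lowercased, whitespace-collapsed, no `*` or qualifiers), `qualifiers`
#'   (list column of character vectors, canonicalized), `major_topic`
#'   (logical), and `raw` (the input).
#' @examples
#' parse_mesh_heading("Kidney Failure, Chronic/*veterinary")
#' @export
parse_mesh_heading <- function(raw) {
  stopifnot(is.character(raw))
  major <- grepl("*", raw, fixed = TRUE)
  parts <- strsplit(gsub("*", "", raw, fixed = TRUE), "/", fixed = TRUE)
  name <- vapply(parts, function(p) normalize_term(p[[1]]), character(1))
  quals <- lapply(parts, function(p) {
    if (length(p) > 1L) normalize_term(p[-1L]) else character(0)
  })
  out <- data.frame(name = name, major_topic = major, raw = raw,
                    stringsAsFactors = FALSE)
  out$qualifiers <- quals
  out[, c("name", "qualifiers", "major_topic", "raw")]
}

#' Format descriptors back into MH field values
#'
#' Inverse of [parse_mesh_heading()]: the major-topic `*` is re-attached to
#' the descriptor name and qualifiers are re-joined with `/`. When the parsed
#' `raw` form is available it is emitted verbatim, so parse/write round-trips
#' are lossless.
#'
#' @param mesh a descriptor data frame as returned by [parse_mesh_heading()]
#'   (the `raw` column may be absent or `NA`).
#' @return Character vector of `MH` field values.
#' @export
format_mesh_heading <- function(mesh) {
  if (is.null(mesh) || nrow(mesh) == 0L) return(character(0))
  raw <- if ("raw" %in% names(mesh)) mesh$raw else rep(NA_character_, nrow(mesh))
  rebuilt <- vapply(seq_len(nrow(mesh)), function(i) {
    nm <- mesh$name[[i]]
    if (isTRUE(mesh$major_topic[[i]])) nm <- paste0("*", nm)
    paste(c(nm, unlist(mesh$qualifiers[[i]])), collapse = "/")
  }, character(1))
  ifelse(is.na(raw), rebuilt, raw)
}

# Field tags retained from MEDLINE flat records; all others are ignored.
.medline_tags <- c("PMID", "TI", "AB", "DP", "MH")

#' Parse MEDLINE flat-format text into a record table
#'
#' Reads the line-oriented MEDLINE export format: each field line is a tag of
#' up to four characters left-justified in a four-character column, followed
#' by `"- "` and the value; continuation lines start with six spaces and are
#' joined to the previous value with a single space; records are separated by
#' one or more blank lines. Only the `PMID`, `TI`, `AB`, `DP` and `MH` fields
#' are retained.
#'
#' The publication year is the first four-digit token of the `DP` field
#' (`NA` when absent). Blocks without a `PMID` are dropped with a warning;
#' any non-blank line that is neither a valid field line nor a continuation
#' is a parse error reporting the offending line number.
#'
#' @param text a single string, a character vector of lines, or (via
#'   [read_medline()]) the contents of a file.
#' @return A [tibble::tibble] with columns `pmid`, `title`, `abstract`,
#'   `year` and a list column `mesh` of descriptor data frames (see
#'   [parse_mesh_heading()]).
#' @seealso [write_medline()], [read_medline()]
#' @export
parse_medline <- function(text) {
  stopifnot(is.character(text))
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  lines <- sub("[ \t\r]+$", "", lines)
  n <- length(lines)
  empty_records <- tibble::tibble(
    pmid = character(0), title = character(0), abstract = character(0),
    year = integer(0), mesh = list()
  )
  if (n == 0L || all(lines == "")) return(empty_records)

  blank <- lines == ""
  field <- grepl("^[A-Z0-9]{1,4} {0,3}-( .*)?$", lines)
  cont <- grepl("^ {6}", lines) & !blank
  bad <- which(!blank & !field & !cont)
  if (length(bad) > 0L) {
    stop(sprintf("malformed MEDLINE field line %d: \"%s\"",
                 bad[1L], lines[bad[1L]]), call. = FALSE)
  }

  # Record id = cumulative count of blank-line separators before each line.
  block <- cumsum(blank)
  keep <- !blank
  tag <- ifelse(field, sub("^([A-Z0-9]{1,4}) {0,3}-.*$", "\\1", lines), NA_character_)
  value <- ifelse(field, sub("^[A-Z0-9]{1,4} {0,3}- ?", "", lines),
                  sub("^ {6}", "", lines))
  # Attach continuations to the owning field line.
  field_idx <- cumsum(field)
  if (any(cont & field_idx == 0L)) {
    stop(sprintf("continuation line %d precedes any field line",
                 which(cont & field_idx == 0L)[1L]), call. = FALSE)
  }

  df <- data.frame(block = block[keep], tag = tag[keep], value = value[keep],
                   fid = field_idx[keep], stringsAsFactors = FALSE)
  joined <- vapply(split(df$value, df$fid), paste, character(1), collapse = " ")
  first <- !duplicated(df$fid)
  fields <- data.frame(block = df$block[first], tag = df$tag[first],
                       value = unname(joined[as.character(df$fid[first])]),
                       stringsAsFactors = FALSE)

  blocks <- split(fields, fields$block)
  records <- lapply(blocks, function(b) {
    get1 <- function(tg) {
      v <- b$value[b$tag == tg]
      if (length(v) == 0L) NA_character_ else v[[1L]]
    }
    pmid <- get1("PMID")
    if (is.na(pmid) || !grepl("^[0-9]+$", pmid)) {
      warning("dropping MEDLINE block without a valid PMID", call. = FALSE)
      return(NULL)
    }
    dp <- get1("DP")
    year <- NA_integer_
    if (!is.na(dp)) {
      m <- regmatches(dp, regexpr("\\b[0-9]{4}\\b", dp))
      if (length(m) == 1L) year <- as.integer(m)
    }
    ti <- get1("TI")
    ab <- get1("AB")
    list(pmid = pmid,
         title = if (is.na(ti)) "" else ti,
         abstract = if (is.na(ab)) "" else ab,
         year = year,
         mesh = parse_mesh_heading(b$value[b$tag == "MH"]))
  })
  records <- unname(Filter(Negate(is.null), records))
  if (length(records) == 0L) return(empty_records)
  tibble::tibble(
    pmid = vapply(records, `[[`, character(1), "pmid"),
    title = vapply(records, `[[`, character(1), "title"),
    abstract = vapply(records, `[[`, character(1), "abstract"),
    year = vapply(records, `[[`, integer(1), "year"),
    mesh = lapply(records, `[[`, "mesh")
  )
}

#' Read MEDLINE records from a file
#'
#' @param path path to a MEDLINE flat-format text file.
#' @inherit parse_medline return
#' @export
read_medline <- function(path) {
  parse_medline(readLines(path, warn = FALSE))
}

#' Write records as MEDLINE flat-format text
#'
#' Emits one block per record with `PMID`, `TI`, `AB` (omitted when empty),
#' `DP` (omitted when the year is missing) and one `MH` line per descriptor,
#' blocks separated by a blank line. [parse_medline()] applied to the output
#' reproduces the input records field for field.
#'
#' @param records a record table as returned by [parse_medline()].
#' @param path optional file path; when given the text is also written there.
#' @return The MEDLINE text as a single string (invisibly when `path` is
#'   given).
#' @export
write_medline <- function(records, path = NULL) {
  stopifnot(is.data.frame(records))
  blocks <- vapply(seq_len(nrow(records)), function(i) {
    out <- c(paste0("PMID- ", records$pmid[[i]]))
    if (nzchar(records$title[[i]])) out <- c(out, paste0("TI  - ", records$title[[i]]))
    if (nzchar(records$abstract[[i]])) out <- c(out, paste0("AB  - ", records$abstract[[i]]))
    if (!is.na(records$year[[i]])) out <- c(out, paste0("DP  - ", records$year[[i]]))
    mh <- format_mesh_heading(records$mesh[[i]])
    if (length(mh) > 0L) out <- c(out, paste0("MH  - ", mh))
    paste(out, collapse = "\n")
  }, character(1))
  text <- if (length(blocks) == 0L) "" else paste0(paste(blocks, collapse = "\n\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Construct a literature corpus
#'
#' Bundles a record table with its provenance (species label, the search
#' string that produced it, retrieval date). Duplicate PMIDs keep the first
#' occurrence; the rest are dropped with a warning. Corpora for different
#' species are analysed independently, so the same PMID may appear in more
#' than one corpus.
#'
#' @param records record table from [parse_medline()] / [read_medline()].
#' @param species_label corpus label, conventionally `"human"`, `"cat"` or
#'   `"dog"`.
#' @param query the search string used to retrieve the corpus, if any.
#' @param retrieved_date ISO date string, if known.
#' @return An object of class `corpus`.
#' @export
corpus <- function(records, species_label, query = NA_character_,
                   retrieved_date = NA_character_) {
  stopifnot(is.data.frame(records), is.character(species_label),
            length(species_label) == 1L, nzchar(species_label))
  if (nrow(records) > 0L) {
    stopifnot(all(grepl("^[0-9]+$", records$pmid)))
    ok_year <- is.na(records$year) | (records$year >= 1800L & records$year <= 2100L)
    if (!all(ok_year)) stop("publication year outside [1800, 2100]", call. = FALSE)
    dup <- duplicated(records$pmid)
    if (any(dup)) {
      warning(sprintf("dropping %d record(s) with duplicate PMIDs: %s",
                      sum(dup), paste(unique(records$pmid[dup]), collapse = ", ")),
              call. = FALSE)
      records <- records[!dup, , drop = FALSE]
    }
  }
  structure(
    list(species_label = species_label, query = query,
         retrieved_date = retrieved_date, records = records),
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %s: %d records", x$species_label, nrow(x$records)))
  yrs <- x$records$year[!is.na(x$records$year)]
  if (length(yrs) > 0L) cat(sprintf(" (%d-%d)", min(yrs), max(yrs)))
  cat("\n")
  invisible(x)
}

#' Read a corpus from a MEDLINE file
#'
#' @inheritParams corpus
#' @param path MEDLINE flat-format file.
#' @return A `corpus`.
#' @export
read_corpus <- function(path, species_label,
                        query = NA_character_, retrieved_date = NA_character_) {
  corpus(read_medline(path), species_label, query, retrieved_date)
}

#' PubMed search strings for the renal-disease corpora
#'
#' The three species-specific queries combining chronic renal insufficiency /
#' chronic kidney failure headings (plus the broader kidney-diseases heading
#' for cats and dogs, whose CKD-specific literature is small) with a species
#' heading.
#'
#' @return Named character vector with elements `human`, `cat`, `dog`.
#' @export
renal_disease_queries <- function() {
  c(
    human = paste(
      "((chronic renal insufficiencies[MeSH Terms]) OR",
      "(chronic renal insufficiency[MeSH Terms]) OR",
      "(Kidney Failure, Chronic[MeSH Terms])) AND",
      "((Humans[MeSH Terms]) OR (Homo sapiens[MeSH Terms]))"),
    cat = paste(
      "((chronic renal insufficiencies[MeSH Terms]) OR",
      "(kidney diseases[MeSH Terms]) OR",
      "(chronic renal insufficiency[MeSH Terms]) OR",
      "(Kidney Failure, Chronic[MeSH Terms])) AND",
      "(felis catus[MeSH Terms])"),
    dog = paste(
      "((chronic renal insufficiencies[MeSH Terms]) OR",
      "(kidney diseases[MeSH Terms]) OR",
      "(chronic renal insufficiency[MeSH Terms]) OR",
      "(Kidney Failure, Chronic[MeSH Terms])) AND",
      "(canis familiaris[MeSH Terms])")
  )
}

#' Build an NCBI E-utilities request URL
#'
#' @param endpoint `"esearch"` or `"efetch"`.
#' @param params named character vector of query parameters (URL-encoded
#'   here).
#' @return The request URL as a string.
#' @keywords internal
eutils_url <- function(endpoint = c("esearch", "efetch"), params) {
  endpoint <- match.arg(endpoint)
  base <- sprintf("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/%s.fcgi", endpoint)
  q <- paste(names(params), vapply(params, utils::URLencode, character(1),
                                   reserved = TRUE), sep = "=", collapse = "&")
  paste0(base, "?", q)
}

#' Fetch a corpus from PubMed (optional, requires network access)
#'
#' Runs an E-utilities `esearch` for the query, then retrieves the matching
#' records in MEDLINE flat format (`rettype=medline`) in batches, with simple
#' retry-and-backoff on transient failures. Entirely optional: every
#' downstream stage accepts MEDLINE files or in-memory corpora instead, and
#' offline analyses should use those.
#'
#' @param query a PubMed query string, e.g. one of
#'   [renal_disease_queries()].
#' @param species_label label for the resulting corpus.
#' @param max_records retrieve at most this many records.
#' @param contact e-mail address passed to NCBI, as their usage policy asks.
#' @param api_key optional NCBI API key.
#' @param batch_size records per `efetch` call.
#' @param retries retry attempts per HTTP request.
#' @return A `corpus`; zero search hits give an empty corpus, not an error.
#' @export
fetch_pubmed <- function(query, species_label = "custom", max_records = 10000L,
                         contact = NULL, api_key = NULL, batch_size = 500L,
                         retries = 3L) {
  stopifnot(is.character(query), length(query) == 1L, max_records >= 0L)
  common <- c(db = "pubmed", tool = "renalmine")
  if (!is.null(contact)) common <- c(common, email = contact)
  if (!is.null(api_key)) common <- c(common, api_key = api_key)

  get_lines <- function(url) {
    for (i in seq_len(retries)) {
      res <- tryCatch(readLines(url, warn = FALSE), error = function(e) e)
      if (!inherits(res, "error")) return(res)
      Sys.sleep(2^i * 0.5)
    }
    stop(sprintf("PubMed request failed after %d attempts: %s",
                 retries, conditionMessage(res)), call. = FALSE)
  }

  search <- get_lines(eutils_url("esearch", c(
    common, term = query, retmax = format(max_records, scientific = FALSE),
    retmode = "json")))
  ids <- jsonlite::fromJSON(paste(search, collapse = "\n"))$esearchresult$idlist
  ids <- utils::head(ids, max_records)
  if (length(ids) == 0L) {
    return(corpus(parse_medline(character(0)), species_label, query,
                  format(Sys.Date())))
  }

  chunks <- split(ids, ceiling(seq_along(ids) / batch_size))
  text <- unlist(lapply(chunks, function(ch) {
    Sys.sleep(if (is.null(api_key)) 0.4 else 0.12)  # NCBI rate limits
    get_lines(eutils_url("efetch", c(
      common, id = paste(ch, collapse = ","),
      rettype = "medline", retmode = "text")))
  }), use.names = FALSE)
  recs <- parse_medline(text)
  recs <- utils::head(recs, max_records)
  corpus(recs, species_label, query, format(Sys.Date()))
}
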