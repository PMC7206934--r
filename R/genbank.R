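#' Read a GenBank flat file
#'
#' Minimal parser for the GenBank flat-file format covering what CDS
#' extraction needs: the accession, the `ORIGIN` sequence, and `CDS`
#' features with their location strings (`join(...)`, `complement(...)`)
#' and `/gene`, `/codon_start` qualifiers. It is not a general feature-table
#' parser.
#'
#' @param path Path to a GenBank flat file (text).
#' @return A list of class `cp_genbank` with elements `accession` (string),
#'   `sequence` (DNA string) and `cds` (tibble: `gene_id`, `location`,
#'   `codon_start`).
#' @seealso [extract_cds()]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)

  acc_line <- grep("^(ACCESSION|LOCUS)", lines, value = TRUE)
  accession <- if (length(acc_line)) strsplit(trimws(acc_line[1]), "\\s+")[[1]][2] else NA_character_

  f_start <- grep("^FEATURES", lines)
  o_start <- grep("^ORIGIN", lines)
  if (!length(f_start) || !length(o_start)) {
    abort("not a GenBank flat file: missing FEATURES or ORIGIN section")
  }

  # sequence: strip coordinates, whitespace, and the trailing // record end
  seq_lines <- lines[(o_start[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_lines <- lines[(f_start[1] + 1):(o_start[1] - 1)]
  # a feature starts with its key at column 6; continuation/qualifier lines
  # are indented to column 22
  key_idx <- grep("^ {5}\\S", feat_lines)
  cds <- list()
  for (k in seq_along(key_idx)) {
    first <- key_idx[k]
    last <- if (k < length(key_idx)) key_idx[k + 1] - 1 else length(feat_lines)
    block <- feat_lines[first:last]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    if (key != "CDS") next
    body <- trimws(c(sub("^ {5}\\S+\\s*", "", block[1]), trimws(block[-1])))
    qual_at <- grep("^/", body)
    loc_end <- if (length(qual_at)) qual_at[1] - 1 else length(body)
    location <- paste(body[seq_len(loc_end)], collapse = "")
    quals <- body[grepl("^/", body)]
    get_qual <- function(name) {
      hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub('^/[^=]+="?|"$', "", hit[1])
    }
    cds[[length(cds) + 1]] <- tibble(
      gene_id = get_qual("gene"),
      location = location,
      codon_start = suppressWarnings(as.integer(get_qual("codon_start"))) %||% NA_integer_
    )
  }
  cds <- if (length(cds)) list_rbind(cds) else
    tibble(gene_id = character(), location = character(), codon_start = integer())
  cds$codon_start[is.na(cds$codon_start)] <- 1L

  structure(list(accession = accession, sequence = sequence, cds = cds),
            class = "cp_genbank")
}

# Parse a GenBank location string into exon spans plus an overall strand.
# Handles: 10..20, complement(10..20), join(a..b,c..d),
# complement(join(...)), and join(complement(...), complement(...)) when all
# parts agree in strand. Mixed strands within one feature are rejected.
parse_gb_location <- function(location) {
  loc <- gsub("[<>\\s]", "", location)
  outer_complement <- FALSE
  if (grepl("^complement\\(.*\\)$", loc)) {
    outer_complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(.*\\)$", loc) || grepl("^order\\(.*\\)$", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  part_comp <- grepl("^complement\\(", parts)
  if (any(part_comp) && !all(part_comp)) {
    abort(sprintf("compound feature with inconsistent strands: %s", location))
  }
  if (any(part_comp) && outer_complement) {
    abort(sprintf("compound feature with inconsistent strands: %s", location))
  }
  per_part_complement <- length(parts) > 0 && all(part_comp)
  parts <- sub("^complement\\((.*)\\)$", "\\1", parts)
  m <- str_match(parts, "^(\\d+)(?:\\.\\.(\\d+))?$")
  if (anyNA(m[, 1])) abort(sprintf("cannot parse location: %s", location))
  spans <- tibble(
    start = as.integer(m[, 2]),
    end = as.integer(ifelse(is.na(m[, 3]), m[, 2], m[, 3]))
  )
  if (any(spans$end < spans$start)) abort(sprintf("inverted span in location: %s", location))
  list(spans = spans, outer_complement = outer_complement,
       per_part_complement = per_part_complement)
}

#' Extract a CDS from a GenBank record as a gene row
#'
#' Concatenates the exons of the named CDS feature in transcript order,
#' reverse-complementing minus-strand features, and applies the annotated
#' reading frame (`/codon_start`) as the gene's `frame_offset`.
#'
#' @param gb A `cp_genbank` object from [read_genbank()], or a path to a
#'   GenBank flat file.
#' @param gene_id Value of the `/gene` qualifier to extract.
#' @return A one-row gene tibble (`gene_id`, `seq`, `source_accession`,
#'   `frame_offset`).
#' @export
extract_cds <- function(gb, gene_id) {
  if (is.character(gb)) gb <- read_genbank(gb)
  if (!inherits(gb, "cp_genbank")) abort("`gb` must be a cp_genbank object or a path")
  hit <- which(gb$cds$gene_id == gene_id)
  if (!length(hit)) {
    abort(sprintf("no CDS feature with gene \"%s\"; available genes: %s",
                  gene_id, paste(unique(gb$cds$gene_id), collapse = ", ")))
  }
  loc <- parse_gb_location(gb$cds$location[hit[1]])
  if (any(loc$spans$end > nchar(gb$sequence))) {
    abort(sprintf("CDS span exceeds sequence length for gene \"%s\"", gene_id))
  }
  pieces <- substring(gb$sequence, loc$spans$start, loc$spans$end)
  if (loc$outer_complement) {
    # complement(join(...)): complement the spliced product as a whole
    seq <- reverse_complement(paste(pieces, collapse = ""))
  } else if (loc$per_part_complement) {
    # join(complement(..), ..): parts already listed in transcript order
    seq <- paste(vapply(pieces, reverse_complement, character(1)), collapse = "")
  } else {
    seq <- paste(pieces, collapse = "")
  }
  validate_genes(tibble(
    gene_id = gene_id,
    seq = seq,
    source_accession = gb$accession %||% NA_character_,
    frame_offset = gb$cds$codon_start[hit[1]] - 1L
  ))
}
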