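#' Validate and order a gene-order table
#'
#' @param table Tibble with columns `chrom`, `start`, `strand`, `symbol`
#'   (and optionally `genome`, `end`). Symbols are upper-cased and rows
#'   sorted by (chrom, start).
#' @return The normalised tibble.
#' @export
as_gene_order <- function(table) {
  need <- c("chrom", "start", "strand", "symbol")
  if (!all(need %in% names(table))) {
    abort(paste0("gene-order table needs columns: ",
                 paste(need, collapse = ", ")))
  }
  if (!all(table$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  out <- as_tibble(table)
  out$symbol <- toupper(out$symbol)
  arrange(out, .data$chrom, .data$start)
}

#' Read per-genome gene-order tables
#'
#' Accepts TSV with a header (`chrom`, `start`, `strand`, `symbol`, ...)
#' or headerless BED-like columns (chrom, start, end, symbol, score,
#' strand).
#'
#' @param path File path.
#' @param genome Genome label stored in the `genome` column (default:
#'   file name).
#' @return A gene-order tibble.
#' @export
read_gene_order <- function(path, genome = basename(path)) {
  first <- readLines(path, n = 1)
  tab <- if (grepl("chrom", first, fixed = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    setNames(bed[, c(1, 2, 3, 4, 6)],
             c("chrom", "start", "end", "symbol", "strand"))
  }
  tab$genome <- genome
  as_gene_order(tab)
}

#' Signed gene neighborhood around an anchor
#'
#' Returns the window of up to `k` genes on each side of the anchor on the
#' anchor's chromosome, with strand signs -- the unit of comparison for
#' synteny-block scoring. Truncated at chromosome ends. An absent anchor
#' yields an empty window (reported, not fatal).
#'
#' @param table A gene-order tibble for one genome.
#' @param anchor Anchor gene symbol.
#' @param k Flank size in genes.
#' @return A tibble `offset` (0 = anchor), `symbol`, `strand`, `signed`
#'   (e.g. `"+TRPM8"`).
#' @export
neighborhood <- function(table, anchor, k = 5) {
  table <- as_gene_order(table)
  anchor <- toupper(anchor)
  hit <- which(table$symbol == anchor)
  if (!length(hit)) {
    inform(paste0("anchor not found: ", anchor))
    return(tibble(offset = integer(), symbol = character(),
                  strand = character(), signed = character()))
  }
  if (length(hit) > 1) abort(paste0("anchor present more than once: ", anchor))
  chr <- table$chrom[hit]
  ct <- table[table$chrom == chr, ]
  i <- which(ct$symbol == anchor)
  lo <- max(1, i - k); hi <- min(nrow(ct), i + k)
  out <- ct[lo:hi, ]
  tibble(offset = lo:hi - i, symbol = out$symbol, strand = out$strand,
         signed = paste0(out$strand, out$symbol))
}

#' Adjacency and relative orientation of two genes
#'
#' Two genes are adjacent when no other gene lies between them on the
#' chromosome. Orientation follows the reading sense of the ordered pair:
#' `(+,+)` and `(-,-)` are head-to-tail, `(+,-)` tail-to-tail, `(-,+)`
#' head-to-head. Genes on different chromosomes are reported as not
#' syntenic.
#'
#' @param table A gene-order tibble for one genome.
#' @param gene_a,gene_b Gene symbols.
#' @return A one-row tibble: `syntenic`, `adjacent`, `orientation`,
#'   `intervening`.
#' @export
adjacency <- function(table, gene_a, gene_b) {
  table <- as_gene_order(table)
  ga <- toupper(gene_a); gb <- toupper(gene_b)
  ia <- which(table$symbol == ga); ib <- which(table$symbol == gb)
  if (!length(ia) || !length(ib)) {
    abort("both genes must be present in the table")
  }
  if (table$chrom[ia] != table$chrom[ib]) {
    return(tibble(syntenic = FALSE, adjacent = FALSE,
                  orientation = NA_character_, intervening = NA_integer_))
  }
  ct <- table[table$chrom == table$chrom[ia], ]
  ia <- which(ct$symbol == ga); ib <- which(ct$symbol == gb)
  left <- min(ia, ib); right <- max(ia, ib)
  sl <- ct$strand[left]; sr <- ct$strand[right]
  orientation <- if (sl == sr) "head-to-tail"
  else if (sl == "+" && sr == "-") "tail-to-tail"
  else "head-to-head"
  tibble(syntenic = TRUE, adjacent = right - left == 1L,
         orientation = orientation,
         intervening = right - left - 1L)
}

# Longest common subsequence length over signed symbols.
signed_lcs <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n || !m) return(0L)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
      else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

flip_window <- function(signed) {
  flipped <- ifelse(startsWith(signed, "+"),
                    sub("^\\+", "-", signed), sub("^-", "+", signed))
  rev(flipped)
}

#' Synteny block score against a reference window
#'
#' The block score is the length of the longest common subsequence of
#' signed gene symbols between a genome's window and the reference window
#' (orientation-sensitive). Because a locus may be assembled on the
#' opposite strand, the reverse-orientation window (order reversed,
#' strands flipped) is also tested and the better score taken.
#'
#' @param reference_window Window tibble from [neighborhood()] (or a
#'   character vector of signed symbols).
#' @param windows A single window, or a named list of windows, to compare.
#' @return A tibble `genome`, `block_score`, `orientation` (`"direct"` or
#'   `"reverse"`), `shared_genes` (list-column).
#' @export
conserved_block <- function(reference_window, windows) {
  as_signed <- function(w) if (is.data.frame(w)) w$signed else as.character(w)
  ref <- as_signed(reference_window)
  if (is.data.frame(windows) || is.character(windows)) {
    windows <- list(query = windows)
  }
  one <- function(w, nm) {
    s <- as_signed(w)
    direct <- signed_lcs(ref, s)
    reverse <- signed_lcs(ref, flip_window(s))
    score <- max(direct, reverse)
    orient <- if (direct >= reverse) "direct" else "reverse"
    shared <- intersect(sub("^[+-]", "", ref), sub("^[+-]", "", s))
    tibble(genome = nm, block_score = as.integer(score),
           orientation = if (score) orient else NA_character_,
           shared_genes = list(shared))
  }
  bind_rows(imap(windows, one))
}

#' Per-genome synteny report around an anchor gene
#'
#' For each genome: whether the anchor is present, its immediate
#' neighbours, the adjacency/orientation relation with a designated
#' partner gene, and the block score of its neighborhood against the
#' reference genome's. A partner can be `present` (and adjacent or not),
#' `absent`, or `unknown` when the genome is flagged as a draft assembly
#' (absence is then not evidence of absence).
#'
#' @param tables Named list of gene-order tibbles (one per genome), or a
#'   single tibble with a `genome` column.
#' @param anchor Anchor gene symbol.
#' @param partner Optional partner gene symbol for the adjacency relation.
#' @param reference_genome Name of the genome whose window anchors the
#'   block comparison (default: first).
#' @param k Flank size.
#' @param draft_genomes Genomes whose assemblies are draft; a missing
#'   partner there is reported `unknown` rather than `absent`.
#' @return A tibble, one row per genome.
#' @export
synteny_report <- function(tables, anchor, partner = NULL,
                           reference_genome = NULL, k = 5,
                           draft_genomes = character()) {
  if (is.data.frame(tables)) {
    stopifnot("genome" %in% names(tables))
    tables <- split(tables, tables$genome)
  }
  reference_genome <- reference_genome %||% names(tables)[1]
  ref_win <- neighborhood(tables[[reference_genome]], anchor, k)
  one <- function(tab, nm) {
    win <- neighborhood(tab, anchor, k)
    found <- nrow(win) > 0
    blk <- if (found) {
      conserved_block(ref_win, setNames(list(win), nm))
    } else {
      tibble(genome = nm, block_score = 0L, orientation = NA_character_,
             shared_genes = list(character()))
    }
    prt <- if (is.null(partner)) {
      tibble(partner_status = NA_character_, adjacent = NA,
             orientation_pair = NA_character_, intervening = NA_integer_)
    } else if (!toupper(partner) %in% tab$symbol) {
      tibble(partner_status = if (nm %in% draft_genomes) "unknown" else "absent",
             adjacent = NA, orientation_pair = NA_character_,
             intervening = NA_integer_)
    } else if (!found) {
      tibble(partner_status = "present", adjacent = NA,
             orientation_pair = NA_character_, intervening = NA_integer_)
    } else {
      adj <- adjacency(tab, anchor, partner)
      tibble(partner_status = "present", adjacent = adj$adjacent,
             orientation_pair = adj$orientation,
             intervening = adj$intervening)
    }
    bind_cols(tibble(genome = nm, anchor_found = found,
                     window_size = nrow(win)),
              prt, blk[, c("block_score", "orientation", "shared_genes")])
  }
  bind_rows(imap(tables, function(tab, nm) one(as_gene_order(tab), nm)))
}
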