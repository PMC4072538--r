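# Package-wide constants (file sorts first so top-level code in later files
# can use them at load time).

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

# strand-collapsed base-pair substitution classes
COLLAPSED_CLASSES <- c("G:C->T:A", "G:C->A:T", "A:T->G:C",
                       "A:T->C:G", "A:T->T:A", "G:C->C:G")

# the 12 directed reference-strand base changes
DIRECTED_CLASSES <- c("A->C", "A->G", "A->T",
                      "C->A", "C->G", "C->T",
                      "G->A", "G->C", "G->T",
                      "T->A", "T->C", "T->G")

# SNP-filter failure codes
REASON_CODES <- c("LOW_EVOLVED_FRAC", "HIGH_ANCESTOR_FRAC",
                  "LOW_DEPTH_EVOLVED", "LOW_DEPTH_ANCESTOR",
                  "STRAND_UNCONFIRMED", "EXCESS_AMBIGUOUS",
                  "EXCESS_DELETION", "NO_ALT")
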