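{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "genome survey report",
  "type": "object",
  "required": ["parameters", "read_qc", "kmer"],
  "properties": {
    "parameters": {
      "type": "object",
      "required": ["k", "error_rate"],
      "properties": {
        "k": {"type": "integer"},
        "error_rate": {"type": "number"},
        "max_compound_gap": {"type": "integer"},
        "gc_window": {"type": "integer"}
      }
    },
    "read_qc": {
      "type": "object",
      "required": ["n_reads", "n_bases", "q20_pct", "q30_pct", "gc_pct",
                   "expected_error_pct"],
      "properties": {
        "n_reads": {"type": "number"},
        "n_bases": {"type": "number"},
        "q20_pct": {"type": "number"},
        "q30_pct": {"type": "number"},
        "gc_pct": {"type": "number"},
        "expected_error_pct": {"type": "number"}
      }
    },
    "kmer": {
      "type": "object",
      "required": ["peak_depth", "low_depth_cutoff", "kmer_number",
                   "genome_size", "revised_genome_size", "heterozygosity",
                   "repeat_ratio"],
      "properties": {
        "peak_depth": {"type": "integer"},
        "low_depth_cutoff": {"type": "integer"},
        "kmer_number": {"type": "number"},
        "genome_size": {"type": "number"},
        "revised_genome_size": {"type": "number"},
        "heterozygosity": {"type": "number"},
        "repeat_ratio": {"type": "number"}
      }
    },
    "assembly": {
      "type": "object",
      "required": ["total_length", "n_contigs", "n50", "n90", "max_contig"],
      "properties": {
        "total_length": {"type": "number"},
        "n_contigs": {"type": "integer"},
        "n50": {"type": "integer"},
        "n90": {"type": "integer"},
        "max_contig": {"type": "integer"}
      }
    },
    "ssr": {
      "type": "object",
      "required": ["n_sequences_examined", "total_examined_bp", "n_ssr",
                   "n_sequences_with_ssr", "n_compound"],
      "properties": {
        "n_sequences_examined": {"type": "integer"},
        "total_examined_bp": {"type": "number"},
        "n_ssr": {"type": "integer"},
        "n_sequences_with_ssr": {"type": "integer"},
        "n_sequences_with_more_than_one": {"type": "integer"},
        "n_compound": {"type": "integer"}
      }
    },
    "mito": {
      "type": "object",
      "required": ["length", "composition"],
      "properties": {
        "length": {"type": "integer"},
        "composition": {"type": "object"},
        "gene_order": {
          "type": "object",
          "required": ["is_canonical"],
          "properties": {"is_canonical": {"type": "boolean"}}
        }
      }
    }
  }
}
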