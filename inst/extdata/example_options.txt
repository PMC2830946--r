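# Example options file: one KEY=value per line, '#' starts a comment,
# keys are case-insensitive. Barcodes are given as BARCODE_<sample>=<seq>.
ADAPTER_B=CTGAGACTGCCAAGGCACAC
ADAPTER_MAX_MISMATCH_FRACTION=0.1
FORWARD_PRIMER=AACCTGGTTGATCCTGCCAGT
REVERSE_PRIMER=TGATCCTTCTGCAGGTTCACCTAC
BARCODE_S1=ACAGTC
BARCODE_S2=CGTCAG
BARCODE_S3=GTACGA
MIN_LEN=100
MAX_LEN=170
MIN_MEAN_QUALITY=20
MIN_COPY_NUMBER=2
BOUNDARY_WINDOW=8
BOUNDARY_MISMATCH_THRESHOLD=3
SIMILARITY_CUTOFF=100
SEED=42
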