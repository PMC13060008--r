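#version=2025-02-01
code	expansion
AB	01|02
AC	01|03
ABC	01|02|03
GK	A*02:01|A*02:05
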