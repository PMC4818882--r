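class	count
complete	581
open5	913
open3	476
open_both	587
coding_total	2557
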