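asthma	Clostridium difficile
asthma	Firmicutes
asthma	Staphylococcus aureus
asthma	Bifidobacterium
asthma	Bifidobacterium
colorectal carcinoma	Helicobacter pylori
colorectal carcinoma	Clostridium difficile
colorectal carcinoma	Lactobacillus
colorectal carcinoma	Proteobacteria
COPD	Helicobacter pylori
COPD	Firmicutes
COPD	Staphylococcus aureus
type 1 diabetes	Bacteroides
type 1 diabetes	Lactobacillus
type 1 diabetes	Clostridium coccoides
psoriasis	Firmicutes
psoriasis	Proteobacteria
psoriasis	Streptococcus
crohn's disease	Bacteroides
crohn's disease	Faecalibacterium prausnitzii
crohn's disease	Clostridium coccoides
crohn's disease	Proteobacteria
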