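{"kappa":2,"codon_freqs":[0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034,0.00783510517246985,0.0246757046718034],"omega":{},"omega_by_class":[0.044,0.118,0.118,0.06,0.06],"site_regime":{},"site_class":[1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1],"switching":[false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false,false],"seed":7,"n_codons":87}
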