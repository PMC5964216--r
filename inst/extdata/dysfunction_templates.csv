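category,block,endpoint,expected
induced-flux-unimpaired,expression,autophagosome,up
induced-flux-unimpaired,expression,adaptor,down
induced-flux-unimpaired,puncta,autophagosome,up
induced-flux-unimpaired,puncta,adaptor,down|no_change
induced-flux-unimpaired,puncta,coloc,no_change
induced-flux-unimpaired,pct_coloc,autophagosome,no_change
induced-flux-unimpaired,pct_coloc,adaptor,no_change
impaired-induction,expression,autophagosome,down
impaired-induction,expression,adaptor,down
impaired-induction,puncta,autophagosome,down
impaired-induction,puncta,adaptor,down|no_change
impaired-induction,puncta,coloc,down
impaired-induction,pct_coloc,autophagosome,no_change
impaired-induction,pct_coloc,adaptor,down
impaired-interaction,expression,autophagosome,down
impaired-interaction,expression,adaptor,up
impaired-interaction,puncta,autophagosome,down|no_change
impaired-interaction,puncta,adaptor,up
impaired-interaction,puncta,coloc,down
impaired-interaction,pct_coloc,autophagosome,down
impaired-interaction,pct_coloc,adaptor,down
failed-fusion,expression,autophagosome,up
failed-fusion,expression,adaptor,up
failed-fusion,puncta,autophagosome,up
failed-fusion,puncta,adaptor,up
failed-fusion,puncta,coloc,up
failed-fusion,pct_coloc,autophagosome,up
failed-fusion,pct_coloc,adaptor,up
optn-failure-exhaustion,expression,autophagosome,any
optn-failure-exhaustion,expression,adaptor,down
optn-failure-exhaustion,puncta,autophagosome,any
optn-failure-exhaustion,puncta,adaptor,down
optn-failure-exhaustion,puncta,coloc,down
optn-failure-exhaustion,pct_coloc,autophagosome,down
optn-failure-exhaustion,pct_coloc,adaptor,up
autophagosome-failure-exhaustion,expression,autophagosome,down
autophagosome-failure-exhaustion,expression,adaptor,up
autophagosome-failure-exhaustion,puncta,autophagosome,down
autophagosome-failure-exhaustion,puncta,adaptor,up
autophagosome-failure-exhaustion,puncta,coloc,down
autophagosome-failure-exhaustion,pct_coloc,autophagosome,up
autophagosome-failure-exhaustion,pct_coloc,adaptor,down
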