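evaluation,model,activity,precision,recall,f1,support,rounding_artifact
holdout,cascade,cough,0.96,0.99,0.98,1688,TRUE
holdout,cascade,fall,1.00,0.98,0.99,200,FALSE
holdout,cascade,sit,0.99,0.93,0.96,1500,FALSE
holdout,cascade,sleep,1.00,0.92,0.96,1500,FALSE
holdout,cascade,walk,0.95,0.96,0.96,1500,TRUE
realtime,flat,cough,0.61,0.88,0.72,2000,FALSE
realtime,flat,fall,0.78,0.66,0.71,300,TRUE
realtime,flat,sit,1.00,0.79,0.88,3000,FALSE
realtime,flat,sleep,0.59,0.65,0.62,3000,FALSE
realtime,flat,walk,0.64,0.88,0.74,3000,FALSE
realtime,cascade,cough,0.98,0.99,0.98,2000,FALSE
realtime,cascade,fall,1.00,0.96,0.98,300,FALSE
realtime,cascade,sit,1.00,0.98,0.99,3000,FALSE
realtime,cascade,sleep,1.00,0.94,0.97,3000,FALSE
realtime,cascade,walk,0.88,1.00,0.94,3000,FALSE
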