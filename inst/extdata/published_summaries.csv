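analysis,task,target,direction,row,mean,ci_low,ci_high,probability
group_diff,delay,SUD,greater,posterior,0.30,0.06,0.54,99
group_diff,delay,SUD,greater,prior,0.37,0.10,0.64,
group_diff,delay,SUD,greater,likelihood,0.24,-0.02,0.51,
group_diff,delay,ND,greater,posterior,0.21,0.03,0.40,99
group_diff,delay,ND,greater,prior,0.37,0.10,0.64,
group_diff,delay,ND,greater,likelihood,0.08,-0.16,0.34,
group_diff,prob_gain,SUD,less,posterior,-0.13,-0.38,0.12,84
group_diff,prob_gain,SUD,less,prior,-0.16,-0.44,0.13,
group_diff,prob_gain,SUD,less,likelihood,-0.09,-0.37,0.19,
group_diff,prob_gain,ND,less,posterior,-0.11,-0.30,0.08,88
group_diff,prob_gain,ND,less,prior,-0.16,-0.44,0.13,
group_diff,prob_gain,ND,less,likelihood,-0.06,-0.33,0.21,
group_diff,prob_loss,SUD,less,posterior,-0.26,-0.49,-0.02,98
group_diff,prob_loss,SUD,less,prior,-0.16,-0.44,0.13,
group_diff,prob_loss,SUD,less,likelihood,-0.27,-0.54,-0.01,
group_diff,prob_loss,ND,less,posterior,-0.19,-0.38,-0.01,98
group_diff,prob_loss,ND,less,prior,-0.16,-0.44,0.13,
group_diff,prob_loss,ND,less,likelihood,-0.21,-0.48,0.04,
group_diff,loss_aversion,SUD,less,posterior,-0.05,-0.29,0.19,65
group_diff,loss_aversion,SUD,less,prior,-0.44,-0.71,-0.17,
group_diff,loss_aversion,SUD,less,likelihood,0.09,-0.18,0.36,
group_diff,loss_aversion,ND,less,posterior,-0.14,-0.33,0.04,93
group_diff,loss_aversion,ND,less,prior,-0.44,-0.71,-0.17,
group_diff,loss_aversion,ND,less,likelihood,0.12,-0.14,0.37,
prediction,delay,sud_criteria,greater,posterior,0.12,0.03,0.20,99
prediction,delay,sud_criteria,greater,prior,0.25,0.00,0.50,
prediction,delay,sud_criteria,greater,likelihood,0.10,0.01,0.20,
prediction,delay,nd_criteria,greater,posterior,0.03,-0.06,0.11,72
prediction,delay,nd_criteria,greater,prior,0.25,0.00,0.50,
prediction,delay,nd_criteria,greater,likelihood,0.00,-0.10,0.09,
prediction,delay,qfi_sud,greater,posterior,0.04,-0.05,0.15,83
prediction,delay,qfi_sud,greater,prior,0.25,0.00,0.50,
prediction,delay,qfi_sud,greater,likelihood,0.11,0.00,0.22,
prediction,delay,qfi_nd,greater,posterior,0.07,-0.03,0.14,93
prediction,delay,qfi_nd,greater,prior,0.25,0.00,0.50,
prediction,delay,qfi_nd,greater,likelihood,0.05,-0.04,0.15,
prediction,prob_gain,sud_criteria,less,posterior,-0.04,-0.13,0.04,84
prediction,prob_gain,sud_criteria,less,prior,-0.25,-0.50,0.00,
prediction,prob_gain,sud_criteria,less,likelihood,-0.02,-0.11,0.08,
prediction,prob_gain,nd_criteria,less,posterior,-0.06,-0.14,0.03,90
prediction,prob_gain,nd_criteria,less,prior,-0.25,-0.50,0.00,
prediction,prob_gain,nd_criteria,less,likelihood,-0.03,-0.12,0.06,
prediction,prob_gain,qfi_sud,less,posterior,0.02,-0.09,0.12,40
prediction,prob_gain,qfi_sud,less,prior,-0.25,-0.50,0.00,
prediction,prob_gain,qfi_sud,less,likelihood,0.00,-0.10,0.10,
prediction,prob_gain,qfi_nd,less,posterior,0.03,-0.08,0.13,29
prediction,prob_gain,qfi_nd,less,prior,-0.25,-0.50,0.00,
prediction,prob_gain,qfi_nd,less,likelihood,0.03,-0.06,0.12,
prediction,prob_loss,sud_criteria,less,posterior,0.02,-0.07,0.10,34
prediction,prob_loss,sud_criteria,less,prior,-0.25,-0.50,0.00,
prediction,prob_loss,sud_criteria,less,likelihood,0.05,-0.04,0.14,
prediction,prob_loss,nd_criteria,less,posterior,-0.09,-0.17,-0.01,98
prediction,prob_loss,nd_criteria,less,prior,-0.25,-0.50,0.00,
prediction,prob_loss,nd_criteria,less,likelihood,-0.06,-0.16,0.03,
prediction,prob_loss,qfi_sud,less,posterior,0.03,-0.07,0.14,26
prediction,prob_loss,qfi_sud,less,prior,-0.25,-0.50,0.00,
prediction,prob_loss,qfi_sud,less,likelihood,0.02,-0.08,0.13,
prediction,prob_loss,qfi_nd,less,posterior,0.03,-0.07,0.13,31
prediction,prob_loss,qfi_nd,less,prior,-0.25,-0.50,0.00,
prediction,prob_loss,qfi_nd,less,likelihood,0.02,-0.08,0.11,
prediction,loss_aversion,sud_criteria,less,posterior,-0.14,-0.23,-0.06,99
prediction,loss_aversion,sud_criteria,less,prior,-0.25,-0.50,0.00,
prediction,loss_aversion,sud_criteria,less,likelihood,-0.13,-0.23,-0.03,
prediction,loss_aversion,nd_criteria,less,posterior,-0.10,-0.18,-0.01,98
prediction,loss_aversion,nd_criteria,less,prior,-0.25,-0.50,0.00,
prediction,loss_aversion,nd_criteria,less,likelihood,-0.07,-0.17,0.03,
prediction,loss_aversion,qfi_sud,less,posterior,-0.02,-0.13,0.09,62
prediction,loss_aversion,qfi_sud,less,prior,-0.25,-0.50,0.00,
prediction,loss_aversion,qfi_sud,less,likelihood,-0.04,-0.16,0.07,
prediction,loss_aversion,qfi_nd,less,posterior,-0.02,-0.10,0.09,57
prediction,loss_aversion,qfi_nd,less,prior,-0.25,-0.50,0.00,
prediction,loss_aversion,qfi_nd,less,likelihood,-0.02,-0.11,0.08,
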